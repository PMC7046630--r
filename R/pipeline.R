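#' End-to-end analysis pipeline on a synthetic cohort pair
#'
#' Runs the full analysis shape on simulated data: cohort-pair generation,
#' probe QC, cell-type deconvolution, covariate residualization, ORM
#' construction, REML variance-share estimation under the four covariate
#' models, the four association engines with their inflation factors,
#' BLUP and thresholded weight tables, out-of-sample profile scores with
#' AUC classification in the target cohort, the cell-proportion stepwise
#' logistic association, and the cross-cohort effect-size correlation.
#' Deterministic given the config seed.
#'
#' @param config A named list (or path to a YAML file) with optional
#'   entries `sim` (arguments to [sim_config()]), `moment` (arguments to
#'   [moment_config()]), `p_thresholds` (scoring grid), `sd_min` (probe
#'   filter), and `out_dir` (write stage artifacts as TSV when set).
#' @return A list of report tables: `counts`, `oreml`, `mwas` (per-engine
#'   lambda and top hits), `auc`, `ctp_assoc`, `rb`; plus the fitted
#'   objects in `objects`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_sim <- do.call(sim_config, config$sim %||% list())
  cfg_moment <- do.call(moment_config, config$moment %||% list())
  p_grid <- config$p_thresholds %||% c(1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
  p_grid <- sort(p_grid)
  sd_min <- config$sd_min %||% 0.02
  out_dir <- config$out_dir

  pair <- simulate_cohort_pair(cfg_sim)
  disc <- pair$discovery
  targ <- pair$target
  counts <- tibble(
    stage = c("simulated_discovery", "simulated_target"),
    n_individuals = c(n_samples(disc$methyl), n_samples(targ$methyl)),
    m_probes = c(n_probes(disc$methyl), n_probes(targ$methyl))
  )

  ref <- disc$truth$reference
  prep <- lapply(list(disc = disc, targ = targ), function(cohort) {
    filt <- filter_probes(cohort$methyl, sd_min = sd_min)
    ctp <- estimate_ctp(filt, ref)
    covars <- c("age", "sex", "smoking_score", "batch", "chip_position")
    resid <- residualize_probes(filt, cohort$samples, covars)
    list(filtered = filt, ctp = ctp, std = standardize_probes(resid),
         samples = cohort$samples)
  })
  counts <- dplyr::bind_rows(counts, tibble(
    stage = c("qc_discovery", "qc_target"),
    n_individuals = c(n_samples(prep$disc$filtered), n_samples(prep$targ$filtered)),
    m_probes = c(n_probes(prep$disc$filtered), n_probes(prep$targ$filtered))
  ))

  y <- prep$disc$samples$status
  orm_d <- compute_orm(prep$disc$std)
  C_conf <- covariate_design(prep$disc$samples,
                             c("age", "sex", "smoking_score", "batch"),
                             intercept = FALSE)
  ctp_cols <- setdiff(names(prep$disc$ctp), "sample_id")
  drop_ct <- if ("eosinophils" %in% ctp_cols) "eosinophils" else ctp_cols[length(ctp_cols)]
  C_ctp <- as.matrix(prep$disc$ctp[, setdiff(ctp_cols, drop_ct)])
  oreml_models <- list(
    none = NULL, confounders = C_conf, ctp = C_ctp,
    confounders_ctp = cbind(C_conf, C_ctp)
  )
  oreml_fits <- lapply(oreml_models, function(C) reml_fit(y, C, list(orm_d)))
  oreml_tab <- dplyr::bind_rows(lapply(names(oreml_fits), function(nm) {
    dplyr::mutate(glance(oreml_fits[[nm]]), model = nm, .before = 1)
  }))

  engines <- list(
    linear = function() mwas_linear(prep$disc$std, y),
    linear_pc = function() mwas_pc_adjusted(prep$disc$std, y, orm = orm_d, k = 10),
    moa = function() mwas_moa(prep$disc$std, y),
    moment = function() mwas_moment(prep$disc$std, y, cfg = cfg_moment)
  )
  mwas_res <- lapply(engines, function(f) f())
  mwas_tab <- dplyr::bind_rows(lapply(mwas_res, glance))

  # scoring: discovery-estimated weights applied to the target cohort
  blup_w <- blup_effects(prep$disc$std, y, C = C_conf)
  fit_ctp <- ctp_fixed_effects(y, C_conf, prep$disc$ctp, orm_d,
                               drop_cell = drop_ct)
  targ_status <- prep$targ$samples$status
  targ_ctp <- prep$targ$ctp
  auc_rows <- list()
  add_auc <- function(label, thr, m_used, scores) {
    cl <- classify_scores(scores, targ_status)
    auc_rows[[length(auc_rows) + 1]] <<-
      dplyr::mutate(cl, method = label, p_threshold = thr, m_used = m_used,
                    .before = 1)
  }
  for (eng in c("moa", "moment")) {
    for (wt in threshold_weights(mwas_res[[eng]], p_grid)) {
      if (nrow(wt) == 0) next
      sc <- mps_score(prep$targ$std, wt)
      add_auc(eng, attr(wt, "p_threshold"), attr(wt, "m_used"), sc$score)
    }
  }
  blup_sc <- mps_score(prep$targ$std, blup_w)
  add_auc("blup", NA_real_, attr(blup_sc, "n_matched"), blup_sc$score)
  ctp_sc <- ctp_score(targ_ctp, fit_ctp$effects)
  add_auc("ctp", NA_real_, nrow(fit_ctp$effects), ctp_sc$score)
  comb <- profile_score(prep$targ$std, weights = blup_w, ctp = targ_ctp,
                        ctp_effects = fit_ctp$effects)
  add_auc("blup_ctp", NA_real_, NA_integer_, comb$mps_total)
  auc_tab <- dplyr::bind_rows(auc_rows)

  ctp_assoc <- stepwise_ctp_logistic(prep$disc$ctp, y)

  mwas_t_lin <- mwas_linear(prep$targ$std, targ_status)
  shared <- intersect(mwas_res$linear$probe_id, mwas_t_lin$probe_id)
  i1 <- match(shared, mwas_res$linear$probe_id)
  i2 <- match(shared, mwas_t_lin$probe_id)
  top <- which(mwas_res$linear$p[i1] < 0.01)
  rb_tab <- tryCatch({
    if (length(top) >= 10) {
      rb_estimate(mwas_res$linear$b[i1][top], mwas_res$linear$se[i1][top],
                  mwas_t_lin$b[i2][top], mwas_t_lin$se[i2][top])
    } else tibble(rb = NA_real_, se = NA_real_, n_probes = length(top),
                  clipped = NA)
  }, error = function(e) tibble(rb = NA_real_, se = NA_real_,
                                n_probes = length(top), clipped = NA))

  report <- list(counts = counts, oreml = oreml_tab, mwas = mwas_tab,
                 auc = auc_tab, ctp_assoc = ctp_assoc, rb = rb_tab,
                 objects = list(mwas = mwas_res, oreml = oreml_fits,
                                blup = blup_w, ctp_effects = fit_ctp$effects,
                                pair = pair, prep = prep))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("counts", "oreml", "mwas", "auc", "ctp_assoc", "rb")) {
      data.table::fwrite(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t")
    }
    for (nm in names(mwas_res)) {
      write_mwas(mwas_res[[nm]], file.path(out_dir, paste0("mwas_", nm, ".tsv")))
    }
  }
  report
}
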