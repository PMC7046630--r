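#' Configuration for the synthetic whole-blood cohort generator
#'
#' Builds the parameter set for [simulate_cohort()] /
#' [simulate_cohort_pair()]. Defaults emulate a 450K-like whole-blood
#' case-control cohort: beta values arise from cell-type mixtures with a
#' case shift in composition (neutrophilia), sparse causal probes with
#' standardized effects in the range reported for blood DNAm disease
#' associations (~0.15 SD), slide-like batch offsets partially confounded
#' with status, and age/sex/smoking covariates.
#'
#' @param n_cases,n_controls Individuals per group.
#' @param m_probes Number of probes.
#' @param n_causal Number of causal probes (0 for a causal-null cohort).
#' @param effect_sd Per-probe standardized case-control difference at causal
#'   probes (SD units of the probe); signs are random per probe.
#' @param cell_types Number of blood cell types K (first is neutrophils).
#' @param ctp_case_shift Length-K vector of case-minus-control mean
#'   proportion differences; must sum to 0. Default shifts neutrophils up
#'   by 1 percentage point, compensated across the remaining types.
#' @param batch_levels Number of slide-like batch levels.
#' @param batch_sd SD of probe-by-batch offsets on the logit scale.
#' @param batch_confounding In `[0, 1]`: 0 assigns batches independently of
#'   status; 1 puts all cases in one half of the batches. Emulates cases and
#'   controls being processed on different slides.
#' @param noise_sd Residual SD on the logit scale.
#' @param frac_low_variance Fraction of probes generated nearly constant
#'   (raw beta SD < 0.02), as on real arrays.
#' @param probe_overlap Fraction of discovery probes present in the target
#'   cohort of a pair.
#' @param ctp_concentration Dirichlet concentration controlling
#'   between-individual cell-proportion variability.
#' @param seed Master seed; per-component streams are spawned from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 400, n_controls = 400,
                       m_probes = 2000, n_causal = 20, effect_sd = 0.15,
                       cell_types = 6,
                       ctp_case_shift = NULL,
                       batch_levels = 20, batch_sd = 0.15,
                       batch_confounding = 0.30,
                       noise_sd = 0.4,
                       frac_low_variance = 0.05,
                       probe_overlap = 1,
                       ctp_concentration = 60,
                       seed = 1L) {
  K <- as.integer(cell_types)
  if (is.null(ctp_case_shift)) {
    ctp_case_shift <- c(0.010, rep(-0.010 / (K - 1), K - 1))
  }
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    m_probes = as.integer(m_probes), n_causal = as.integer(n_causal),
    effect_sd = effect_sd, cell_types = K,
    ctp_case_shift = ctp_case_shift,
    batch_levels = as.integer(batch_levels), batch_sd = batch_sd,
    batch_confounding = batch_confounding,
    noise_sd = noise_sd, frac_low_variance = frac_low_variance,
    probe_overlap = probe_overlap,
    ctp_concentration = ctp_concentration,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cases < 1 || n_controls < 1 || m_probes < 1 || batch_levels < 1) {
      abort("counts in sim_config must be positive.")
    }
    if (n_causal < 0 || n_causal > m_probes) {
      abort("need 0 <= n_causal <= m_probes.")
    }
    if (length(ctp_case_shift) != cell_types) {
      abort("`ctp_case_shift` must have one entry per cell type.")
    }
    if (abs(sum(ctp_case_shift)) > 1e-10) {
      abort("`ctp_case_shift` must sum to 0 (proportions stay a composition).")
    }
    if (probe_overlap < 0 || probe_overlap > 1) abort("`probe_overlap` must be in [0, 1].")
    if (frac_low_variance < 0 || frac_low_variance >= 1) {
      abort("`frac_low_variance` must be in [0, 1).")
    }
    if (batch_confounding < 0 || batch_confounding > 1) {
      abort("`batch_confounding` must be in [0, 1].")
    }
  })
  invisible(cfg)
}

blood_cell_names <- function(K) {
  base <- c("neutrophils", "CD4T", "CD8T", "Bcells", "NK", "monocytes",
            "eosinophils", "basophils")
  if (K <= length(base)) base[seq_len(K)] else c(base, paste0("cell", seq_len(K - length(base))))
}

blood_cell_means <- function(K) {
  base <- c(0.55, 0.15, 0.09, 0.06, 0.06, 0.09)
  if (K == 6) return(base)
  p <- rgamma(K, shape = 2) # only used for non-default K
  p / sum(p)
}

# Spawn reproducible per-component sub-seeds from one master seed.
spawn_seeds <- function(seed, labels) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(labels)), labels)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a cell-type methylation reference panel
#'
#' Generates mean beta values of `K` purified blood cell types over `m`
#' probes. Each probe has a shared baseline on the logit scale plus
#' cell-type-specific deviations, giving a signature matrix of full rank K.
#'
#' @param K Number of cell types (>= 2).
#' @param m Number of probes (>= K).
#' @param seed Integer seed.
#' @param cell_names Optional character vector of cell-type names.
#' @return A `K x m` matrix of class `cell_reference`, entries in `[0, 1]`,
#'   rownames cell types, colnames probe ids.
#' @export
simulate_cell_reference <- function(K, m, seed = 1L, cell_names = NULL) {
  K <- as.integer(K); m <- as.integer(m)
  if (K < 2) abort("need at least K = 2 cell types.")
  if (K > m) abort("invalid configuration: K cell types need at least K probes.")
  if (is.null(cell_names)) cell_names <- blood_cell_names(K)
  ref <- with_seed(seed, {
    # probe baseline on the logit scale, clipped so baseline-driven probes
    # keep visible between-individual variance (near-constant probes are a
    # separate, explicitly configured class in the cohort generator)
    base <- pmin(pmax(rnorm(m, 0, 1.5), -2), 2)
    dev <- matrix(rnorm(K * m, 0, 0.8), K, m)     # cell-specific signatures
    plogis(sweep(dev, 2, base, `+`))
  })
  dimnames(ref) <- list(cell_names, sprintf("cg%07d", seq_len(m)))
  structure(ref, class = c("cell_reference", "matrix", "array"))
}

# Probe genomic annotation: 22 autosomes, sequential positions with
# 20-60 kb gaps so neighbouring probes often fall within a 50 kb half-window.
simulate_probe_annot <- function(probe_ids, seed) {
  m <- length(probe_ids)
  with_seed(seed, {
    chr <- sort(sample(1:22, m, replace = TRUE,
                       prob = (23 - (1:22)) / sum(23 - (1:22))))
    bp <- integer(m)
    for (c_i in unique(chr)) {
      idx <- which(chr == c_i)
      gaps <- round(runif(length(idx), 2e4, 6e4))
      bp[idx] <- 1e6 + cumsum(gaps)
    }
    tibble(
      probe_id = probe_ids,
      chr = as.character(chr),
      bp = as.integer(bp),
      gene = sprintf("GENE%04d", sample.int(max(2L, m %/% 2), m, replace = TRUE)),
      orientation = sample(c("F", "R"), m, replace = TRUE)
    )
  })
}

# Dirichlet draws with per-individual mean vectors.
rdirichlet_rows <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = pmax(alpha, 1e-8)), nrow = nrow(alpha))
  g / rowSums(g)
}

#' Simulate a case-control whole-blood methylation cohort
#'
#' Beta values are built as `plogis(qlogis(mixture) + batch + covariate
#' effects + causal shift + noise)`: the cell-type mixture is taken through
#' the logit, probe-by-batch offsets and residual noise are added on that
#' scale, causal probes receive a case shift calibrated so the realized
#' case-control difference is `effect_sd` standard deviations of the probe,
#' and the sum is squashed back to `[0, 1]`. Case cell-type composition is
#' shifted by `ctp_case_shift`, which propagates into every probe carrying
#' a cell-type signature — the confounding that mixed-model association
#' engines are designed to absorb.
#'
#' @param config A [sim_config()].
#' @param reference Optional `cell_reference` with at least `m_probes`
#'   probes; generated from the config seed when `NULL`.
#' @param shared Optional list of components shared across cohorts of a
#'   pair (internal; see [simulate_cohort_pair()]).
#' @param seed_offset Integer added to the master seed stream, used to
#'   generate independent individuals in the target cohort of a pair.
#'
#' @return A list with elements `methyl` (a beta-scale [methyl_set()]),
#'   `samples` (tibble: sample_id, status, age, sex, smoking_score, batch,
#'   chip_position) and `truth` (causal probe ids and effects, true cell
#'   proportions, realized variance share `true_rho2`, batch assignment).
#' @export
simulate_cohort <- function(config, reference = NULL, shared = NULL,
                            seed_offset = 0L) {
  validate_sim_config(config)
  K <- config$cell_types
  m <- config$m_probes
  n <- config$n_cases + config$n_controls
  seeds <- spawn_seeds(config$seed + seed_offset,
                       c("reference", "annot", "structure", "proportions",
                         "covariates", "batch", "effects", "noise"))

  if (is.null(reference) && !is.null(shared$reference)) reference <- shared$reference
  if (is.null(reference)) {
    reference <- simulate_cell_reference(K, m, seed = seeds[["reference"]])
  }
  if (ncol(reference) < m) abort("reference has fewer probes than m_probes.")
  ref <- unclass(reference)[, seq_len(m), drop = FALSE]
  probe_ids <- colnames(ref)

  probe_annot <- shared$probe_annot %||% simulate_probe_annot(probe_ids, seeds[["annot"]])

  # Probe roles: low-variance probes are near-constant; causal probes are
  # drawn from the remainder. Covariate-responsive probe sets add realistic
  # age/smoking structure.
  structure_bits <- shared$structure %||% with_seed(seeds[["structure"]], {
    n_low <- floor(config$frac_low_variance * m)
    low_idx <- sort(sample.int(m, n_low))
    eligible <- setdiff(seq_len(m), low_idx)
    if (config$n_causal > length(eligible)) {
      abort("too many causal probes for the non-constant probe pool.")
    }
    causal_idx <- sort(sample(eligible, config$n_causal))
    list(
      low_idx = low_idx,
      causal_idx = causal_idx,
      age_idx = sample(eligible, max(1L, round(0.1 * m))),
      age_coef = rnorm(max(1L, round(0.1 * m)), 0, 0.008),
      smoke_idx = sample(eligible, max(1L, round(0.05 * m))),
      smoke_coef = rnorm(max(1L, round(0.05 * m)), 0, 0.15)
    )
  })

  effects <- shared$effects %||% with_seed(seeds[["effects"]], {
    if (config$n_causal == 0) numeric(0)
    else config$effect_sd * sample(c(-1, 1), config$n_causal, replace = TRUE)
  })

  status <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  samp_ids <- sprintf("S%05d", seq_len(n) + seed_offset * 0L)

  ctp <- with_seed(seeds[["proportions"]], {
    means <- matrix(rep(blood_cell_means(K), each = n), n, K)
    means <- means + outer(status, config$ctp_case_shift)
    means <- pmax(means, 1e-3)
    means <- means / rowSums(means)
    rdirichlet_rows(means * config$ctp_concentration)
  })
  colnames(ctp) <- rownames(ref)

  covars <- with_seed(seeds[["covariates"]], {
    tibble(
      sample_id = samp_ids,
      status = status,
      age = round(rnorm(n, 60, 10) + 2 * status, 1),
      sex = rbinom(n, 1, 0.5),
      smoking_score = rnorm(n, 0, 1) + 0.25 * status,
      chip_position = sample(sprintf("P%d", 1:8), n, replace = TRUE)
    )
  })

  batch_bits <- with_seed(seeds[["batch"]], {
    B <- config$batch_levels
    half1 <- seq_len(ceiling(B / 2))
    p_half1 <- 0.5 + config$batch_confounding / 2
    in_half1 <- ifelse(status == 1, rbinom(n, 1, p_half1), rbinom(n, 1, 1 - p_half1))
    assignment <- integer(n)
    assignment[in_half1 == 1] <- sample(half1, sum(in_half1), replace = TRUE)
    assignment[in_half1 == 0] <- sample(setdiff(seq_len(B), half1),
                                        n - sum(in_half1), replace = TRUE)
    offsets <- matrix(rnorm(B * m, 0, config$batch_sd), B, m)
    list(assignment = assignment, offsets = offsets)
  })

  # Assemble on the logit scale.
  mix <- ctp %*% ref
  L <- qlogis(pmin(pmax(mix, 1e-6), 1 - 1e-6))
  L <- L + batch_bits$offsets[batch_bits$assignment, , drop = FALSE]
  age_c <- covars$age - mean(covars$age)
  L[, structure_bits$age_idx] <- L[, structure_bits$age_idx] +
    outer(age_c, structure_bits$age_coef)
  L[, structure_bits$smoke_idx] <- L[, structure_bits$smoke_idx] +
    outer(covars$smoking_score, structure_bits$smoke_coef)

  low_idx <- structure_bits$low_idx
  if (length(low_idx) > 0) {
    # near-constant probes: fixed well-methylated level, tiny logit noise
    L[, low_idx] <- matrix(qlogis(0.92), n, length(low_idx))
  }

  noise <- with_seed(seeds[["noise"]], {
    E <- matrix(rnorm(n * m, 0, config$noise_sd), n, m)
    if (length(low_idx) > 0) E[, low_idx] <- E[, low_idx] * (0.02 / config$noise_sd)
    E
  })
  L <- L + noise

  causal_idx <- structure_bits$causal_idx
  if (length(causal_idx) > 0) {
    # calibrate each causal probe's logit shift so the realized beta-scale
    # case-control difference is `effect` SDs of the probe: Newton steps on
    # f(delta) = E[plogis(L + delta) - plogis(L)] = effect * sd(beta)
    for (jj in seq_along(causal_idx)) {
      j <- causal_idx[jj]
      lj <- L[, j]
      bj <- plogis(lj)
      target <- effects[jj] * sd(bj)
      gprime <- mean(bj * (1 - bj))
      delta <- target / gprime
      for (step in 1:3) {
        f <- mean(plogis(lj + delta) - bj) - target
        fp <- mean(plogis(lj + delta) * (1 - plogis(lj + delta)))
        delta <- delta - f / fp
      }
      L[status == 1, j] <- L[status == 1, j] + delta
    }
  }

  beta <- plogis(L)
  dimnames(beta) <- list(samp_ids, probe_ids)

  P <- mean(status)
  true_rho2 <- min(1, P * (1 - P) * sum(effects^2))

  batch_tab <- covars
  batch_tab$batch <- sprintf("B%02d", batch_bits$assignment)
  batch_tab <- batch_tab[, c("sample_id", "status", "age", "sex",
                             "smoking_score", "batch", "chip_position")]

  list(
    methyl = methyl_set(beta, probe_annot, scale_state = "beta"),
    samples = batch_tab,
    truth = list(
      causal_probe_ids = probe_ids[causal_idx],
      true_effects = setNames(effects, probe_ids[causal_idx]),
      true_ctp = as_tibble(ctp) |>
        dplyr::mutate(sample_id = samp_ids, .before = 1),
      true_rho2 = true_rho2,
      batch_assignment = setNames(batch_bits$assignment, samp_ids),
      reference = structure(ref, class = c("cell_reference", "matrix", "array")),
      probe_annot = probe_annot,
      shared = list(reference = structure(ref, class = c("cell_reference", "matrix", "array")),
                    probe_annot = probe_annot,
                    structure = structure_bits,
                    effects = effects)
    )
  )
}

#' Simulate a discovery/target cohort pair with shared probe effects
#'
#' The two cohorts share the cell-type reference, probe annotation, and
#' causal probe effects, but consist of independent individuals with
#' independent batch and noise draws. The target cohort retains a random
#' subset of `probe_overlap * m` discovery probes, emulating partial probe
#' overlap between arrays processed in different labs.
#'
#' @param config A [sim_config()].
#' @param target_n_cases,target_n_controls Target cohort sizes; default to
#'   the discovery sizes.
#' @return A list with elements `discovery` and `target`, each as returned
#'   by [simulate_cohort()].
#' @export
simulate_cohort_pair <- function(config, target_n_cases = NULL,
                                 target_n_controls = NULL) {
  validate_sim_config(config)
  discovery <- simulate_cohort(config)
  cfg_t <- config
  cfg_t$n_cases <- as.integer(target_n_cases %||% config$n_cases)
  cfg_t$n_controls <- as.integer(target_n_controls %||% config$n_controls)
  target <- simulate_cohort(cfg_t, shared = discovery$truth$shared,
                            seed_offset = 104729L)
  # rename target individuals so ids never collide with discovery
  tn <- nrow(target$methyl$values)
  new_ids <- sprintf("T%05d", seq_len(tn))
  rownames(target$methyl$values) <- new_ids
  target$samples$sample_id <- new_ids
  target$truth$true_ctp$sample_id <- new_ids
  names(target$truth$batch_assignment) <- new_ids

  m <- config$m_probes
  keep_m <- round(config$probe_overlap * m)
  keep <- with_seed(spawn_seeds(config$seed, "overlap")[[1]],
                    sort(sample.int(m, keep_m)))
  target$methyl <- subset_probes(target$methyl, keep)
  kept_ids <- target$methyl$probe_annot$probe_id
  target$truth$causal_probe_ids <-
    intersect(target$truth$causal_probe_ids, kept_ids)
  target$truth$true_effects <-
    target$truth$true_effects[names(target$truth$true_effects) %in% kept_ids]
  list(discovery = discovery, target = target)
}

#' Simulate a trait from the genome-wide random-probe-effect model
#'
#' Draws `y = W u + e` with joint probe effects `u ~ N(0, sigma_o^2 / m)`
#' and residuals scaled so the genome-wide methylome accounts for a chosen
#' fraction `rho2` of the trait variance. Used for parameter-recovery
#' studies of the REML variance-share estimator.
#'
#' @param W Standardized individuals-x-probes matrix (or `methyl_set`).
#' @param rho2 Target variance fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return Numeric trait vector of length `nrow(W)`.
#' @export
simulate_oreml_trait <- function(W, rho2, seed = 1L) {
  if (inherits(W, "methyl_set")) W <- W$values
  if (rho2 < 0 || rho2 >= 1) abort("`rho2` must be in [0, 1).")
  m <- ncol(W)
  with_seed(seed, {
    u <- rnorm(m, 0, sqrt(rho2 / m))
    e <- rnorm(nrow(W), 0, sqrt(1 - rho2))
    drop(W %*% u) + e
  })
}
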