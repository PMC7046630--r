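#' BLUP estimates of joint probe effects
#'
#' Best linear unbiased prediction of all probe effects jointly under the
#' genome-wide random-effect model:
#' `u_hat = sigma_u^2 W' V^-1 (y - C beta_hat)` with
#' `sigma_u^2 = sigma_o^2 / m`, equivalent to the ridge closed form
#' `W'(WW' + (sigma_e^2 / sigma_u^2) I)^-1 (y - C beta_hat)`. The
#' shrunken effects serve as weights for out-of-sample methylation
#' profile scores.
#'
#' @param m A standardized [methyl_set()] (discovery cohort).
#' @param y Case-control status (0/1).
#' @param C Optional covariate matrix (age, sex, smoking score, batch
#'   indicators, ...).
#' @param reml Optional precomputed null-model [reml_fit()] on the ORM of
#'   `m` with the same covariates.
#' @return A weight table tibble (`probe_id`, `weight`, `source = "blup"`)
#'   with attribute `m_used`.
#' @export
blup_effects <- function(m, y, C = NULL, reml = NULL) {
  check_standardized(m)
  W <- m$values
  n <- nrow(W)
  orm <- compute_orm(m)
  if (is.null(reml)) reml <- reml_fit(y, C, list(orm))
  if (!reml$converged) warn("REML did not converge; BLUP weights use last estimates.")
  X <- build_fixed_design(C, n)
  resid <- y - drop(X %*% reml$beta_hat[colnames(X)])
  sigma_u2 <- reml$sigma2[["orm1"]] / ncol(W)
  V <- reml$sigma2[["orm1"]] * orm$A + diag(reml$sigma2[["residual"]], n)
  u <- sigma_u2 * drop(crossprod(W, solve(V, resid)))
  out <- tibble(probe_id = colnames(W), weight = u, source = "blup")
  attr(out, "m_used") <- ncol(W)
  out
}

#' Threshold MWAS results into weight tables
#'
#' One weight table per p-value threshold, using the MWAS effect size as
#' the scoring weight for every probe passing the threshold.
#'
#' @param mwas An MWAS tibble.
#' @param p_thresholds Numeric vector of p-value cutoffs.
#' @return A named list of weight tables (`probe_id`, `weight`, `source`),
#'   each with attributes `p_threshold` and `m_used`.
#' @export
threshold_weights <- function(mwas, p_thresholds) {
  method <- attr(mwas, "method") %||% "mwas"
  out <- lapply(p_thresholds, function(thr) {
    sel <- mwas[mwas$p < thr, ]
    if (nrow(sel) == 0) warn(sprintf("no probes pass p < %g.", thr))
    wt <- tibble(probe_id = sel$probe_id, weight = sel$b, source = method)
    attr(wt, "p_threshold") <- thr
    attr(wt, "m_used") <- nrow(wt)
    wt
  })
  names(out) <- formatC(p_thresholds, format = "g")
  out
}

#' Methylation profile scores in a target cohort
#'
#' Per-individual weighted sum of probe values over the probes shared
#' between the weight table and the target cohort. Target probes are
#' standardized within the target sample (an external cohort has no access
#' to the discovery scaler). Unmatched weight probes are counted, not an
#' error.
#'
#' @param target A [methyl_set()] (beta or standardized scale).
#' @param weights A weight table (`probe_id`, `weight`).
#' @return Tibble `sample_id`, `score`, with attributes `n_matched` and
#'   `n_missing`.
#' @export
mps_score <- function(target, weights) {
  shared <- intersect(weights$probe_id, colnames(target$values))
  if (length(shared) == 0) abort("no weight probes present in the target cohort.")
  sub <- subset_probes(target, shared)
  if (sub$scale_state == "beta") sub <- standardize_probes(sub)
  w <- weights$weight[match(shared, weights$probe_id)]
  out <- tibble(sample_id = sample_ids(sub),
                score = drop(sub$values %*% w))
  attr(out, "n_matched") <- length(shared)
  attr(out, "n_missing") <- nrow(weights) - length(shared)
  out
}

#' Cell-composition component of a profile score
#'
#' `score_i = sum_k pi_ik beta_k` over the cell types with estimated
#' fixed effects (see [ctp_fixed_effects()]).
#'
#' @param ctp Tibble from [estimate_ctp()].
#' @param effects Tibble with `cell_type` and `estimate` columns.
#' @return Tibble `sample_id`, `score`.
#' @export
ctp_score <- function(ctp, effects) {
  missing_ct <- setdiff(effects$cell_type, names(ctp))
  if (length(missing_ct) > 0) {
    abort(paste0("cell types absent from proportions table: ",
                 paste(missing_ct, collapse = ", ")))
  }
  P <- as.matrix(ctp[, effects$cell_type, drop = FALSE])
  tibble(sample_id = ctp$sample_id, score = drop(P %*% effects$estimate))
}

#' Combined methylation profile score
#'
#' Sums a probe-weight component and a cell-composition component
#' (each optional) into a per-individual profile score; the components are
#' derived separately, not jointly refit.
#'
#' @param target A [methyl_set()] for the probe component.
#' @param weights Optional weight table for [mps_score()].
#' @param ctp,ctp_effects Optional inputs for [ctp_score()].
#' @return Tibble `sample_id`, `mps_probe`, `mps_ctp`, `mps_total`.
#' @export
profile_score <- function(target, weights = NULL, ctp = NULL,
                          ctp_effects = NULL) {
  if (is.null(weights) && is.null(ctp)) abort("supply weights and/or ctp inputs.")
  out <- tibble(sample_id = sample_ids(target), mps_probe = 0, mps_ctp = 0)
  if (!is.null(weights)) {
    pr <- mps_score(target, weights)
    out$mps_probe <- pr$score[match(out$sample_id, pr$sample_id)]
  }
  if (!is.null(ctp)) {
    if (is.null(ctp_effects)) abort("`ctp_effects` required with `ctp`.")
    cs <- ctp_score(ctp, ctp_effects)
    out$mps_ctp <- cs$score[match(out$sample_id, cs$sample_id)]
  }
  out$mps_total <- out$mps_probe + out$mps_ctp
  out
}

# Midrank (Mann-Whitney) AUC and DeLong variance components.
auc_delong <- function(scores, status) {
  x <- scores[status == 1]  # cases
  y <- scores[status == 0]  # controls
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  auc <- (sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # placements
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rx) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - ry) / n1
  var_auc <- var(v10) / n1 + var(v01) / n0
  list(auc = auc, var = var_auc)
}

#' Classification performance of a profile score
#'
#' AUC by the midrank Mann-Whitney estimator with a DeLong 95% confidence
#' interval, plus a univariate logistic regression of status on the
#' standardized score (odds ratio per score SD, Wald p). Optionally the
#' logistic model can adjust for covariates.
#'
#' @param scores Per-individual numeric scores (or a tibble with a
#'   `score`/`mps_total` column and `sample_id`).
#' @param status 0/1 case-control status aligned to `scores`.
#' @param C Optional covariate matrix for an adjusted logistic model.
#' @return One-row tibble: `auc`, `auc_se`, `ci_lower`, `ci_upper`,
#'   `or_per_sd`, `or_ci_lower`, `or_ci_upper`, `p_logistic`, `n_cases`,
#'   `n_controls`.
#' @export
classify_scores <- function(scores, status, C = NULL) {
  if (is.data.frame(scores)) {
    col <- intersect(c("score", "mps_total"), names(scores))[1]
    if (is.na(col)) abort("score tibble needs a `score` or `mps_total` column.")
    scores <- scores[[col]]
  }
  status <- as.integer(status)
  if (length(unique(status)) < 2) abort("both classes must be present.")
  dl <- auc_delong(scores, status)
  se <- sqrt(dl$var)
  z <- qnorm(0.975)
  s_sd <- sd(scores)
  if (s_sd > 0) {
    zscore <- (scores - mean(scores)) / s_sd
    df <- data.frame(status = status, zscore = zscore)
    fml <- if (is.null(C)) status ~ zscore else status ~ zscore + C
    fit <- glm(fml, family = binomial(), data = df)
    cf <- summary(fit)$coefficients["zscore", , drop = FALSE]
  } else {
    cf <- matrix(NA_real_, 1, 4)  # degenerate constant score
  }
  tibble(
    auc = dl$auc, auc_se = se,
    ci_lower = max(0, dl$auc - z * se), ci_upper = min(1, dl$auc + z * se),
    or_per_sd = exp(cf[1, 1]),
    or_ci_lower = exp(cf[1, 1] - z * cf[1, 2]),
    or_ci_upper = exp(cf[1, 1] + z * cf[1, 2]),
    p_logistic = cf[1, 4],
    n_cases = sum(status == 1), n_controls = sum(status == 0)
  )
}
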