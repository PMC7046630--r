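#' Error-corrected correlation of effect sizes between two MWAS
#'
#' Estimates the correlation of true probe effects underlying two sets of
#' estimated effects, correcting the denominator for estimation-error
#' variance:
#' `r_b = cov(b1, b2) / sqrt((var(b1) - mean(se1^2)) (var(b2) - mean(se2^2)))`.
#' Unlike the naive Pearson correlation, which is attenuated toward zero
#' by sampling error in both inputs, `r_b` is consistent for the
#' correlation of the true effects. The standard error comes from a
#' delete-one jackknife over probes. For samples with overlapping
#' individuals a covariance correction would also be needed; the two
#' cohorts compared here are independent, so none is applied.
#'
#' @param b1,b2 Estimated effects (equal length, >= 10).
#' @param se1,se2 Their standard errors.
#' @return One-row tibble: `rb`, `se`, `n_probes`, `clipped`.
#' @export
rb_estimate <- function(b1, se1, b2, se2) {
  k <- length(b1)
  if (k < 10) abort("need at least 10 probes for an r_b estimate.")
  if (length(b2) != k || length(se1) != k || length(se2) != k) {
    abort("all four inputs must have equal length.")
  }
  if (any(!is.finite(c(b1, b2, se1, se2))) || any(c(se1, se2) <= 0)) {
    abort("effects must be finite and standard errors positive.")
  }
  est <- rb_point(b1, se1, b2, se2)
  jack <- vapply(seq_len(k), function(i) {
    rb_point(b1[-i], se1[-i], b2[-i], se2[-i], clip = TRUE)
  }, numeric(1))
  se <- sqrt((k - 1) / k * sum((jack - mean(jack))^2))
  clipped <- est < -1 || est > 1
  tibble(rb = min(1, max(-1, est)), se = se, n_probes = k, clipped = clipped)
}

rb_point <- function(b1, se1, b2, se2, clip = FALSE) {
  v1 <- var(b1) - mean(se1^2)
  v2 <- var(b2) - mean(se2^2)
  if (v1 <= 0 || v2 <= 0) {
    if (clip) return(NA_real_)
    abort("error-corrected variance is non-positive; signal dominated by noise.")
  }
  r <- stats::cov(b1, b2) / sqrt(v1 * v2)
  if (clip) min(1, max(-1, r)) else r
}

#' Stepwise backward logistic regression of status on cell proportions
#'
#' Starts from the full model with all cell types and iteratively removes
#' the term with the largest Wald p-value until every remaining term has
#' p below the stay threshold. Odds ratios are reported per one
#' percentage-point increase in the cell proportion, with Wald 95%
#' confidence intervals; terms passing Bonferroni correction across the K
#' initial tests are flagged.
#'
#' @param ctp Tibble from [estimate_ctp()] (`sample_id` + proportions).
#' @param status 0/1 status aligned to the rows of `ctp`.
#' @param units `"fraction"` (default, converted to percent internally) or
#'   `"percent"` if proportions are already on the 0-100 scale.
#' @param alpha_stay Stay threshold for backward elimination (0.05).
#' @return Tibble: `cell_type`, `or`, `ci_lower`, `ci_upper`, `p`,
#'   `retained`, `bonferroni`. Eliminated cell types keep their last
#'   estimates before removal, with `retained = FALSE`.
#' @export
stepwise_ctp_logistic <- function(ctp, status, units = c("fraction", "percent"),
                                  alpha_stay = 0.05) {
  units <- match.arg(units)
  status <- as.integer(status)
  if (length(unique(status)) < 2) abort("both classes must be present.")
  P <- as.matrix(ctp[, setdiff(names(ctp), "sample_id"), drop = FALSE])
  if (units == "fraction") P <- 100 * P
  K <- ncol(P)
  cells <- colnames(P)
  active <- cells
  dropped <- list()
  repeat {
    df <- data.frame(status = status, P[, active, drop = FALSE])
    fit <- glm(status ~ ., family = binomial(), data = df)
    if (any(fit$fitted.values > 1 - 1e-10) && any(fit$fitted.values < 1e-10)) {
      abort("complete separation in the logistic model; use an exact or penalized method.")
    }
    cf <- summary(fit)$coefficients
    cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
    worst <- which.max(cf[, 4])
    if (cf[worst, 4] <= alpha_stay || nrow(cf) == 1) {
      if (cf[worst, 4] > alpha_stay) {
        dropped[[rownames(cf)[worst]]] <- cf[worst, ]
        cf <- cf[0, , drop = FALSE]
      }
      break
    }
    dropped[[rownames(cf)[worst]]] <- cf[worst, ]
    active <- setdiff(active, rownames(cf)[worst])
  }
  z <- qnorm(0.975)
  row_of <- function(nm, est, retained) {
    est <- unname(est)
    tibble(cell_type = nm, or = exp(est[1]),
           ci_lower = exp(est[1] - z * est[2]),
           ci_upper = exp(est[1] + z * est[2]),
           p = est[4], retained = retained,
           bonferroni = est[4] < 0.05 / K)
  }
  kept <- if (nrow(cf) > 0) {
    dplyr::bind_rows(lapply(rownames(cf), function(nm) row_of(nm, cf[nm, ], TRUE)))
  } else tibble()
  gone <- if (length(dropped) > 0) {
    dplyr::bind_rows(lapply(names(dropped), function(nm) row_of(nm, dropped[[nm]], FALSE)))
  } else tibble()
  out <- dplyr::bind_rows(kept, gone)
  out[match(intersect(cells, out$cell_type), out$cell_type), ]
}

#' Replication sample size for a standardized mean difference
#'
#' Normal-approximation two-sample sample size for detecting a
#' standardized case-control difference `d` at significance `alpha` with
#' the given power, assuming a balanced design:
#' `n_per_group = 2 (z_{1-alpha/2} + z_{power})^2 / d^2` (two-sided;
#' `z_{1-alpha}` for one-sided), total `2 n` rounded up.
#'
#' @param effect_sd_units Standardized effect size d (> 0).
#' @param alpha Significance threshold.
#' @param power Target power.
#' @param sided `"two"` (default) or `"one"`.
#' @return One-row tibble: `n_per_group`, `n_total`.
#' @export
replication_n <- function(effect_sd_units, alpha = 0.05, power = 0.8,
                          sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (effect_sd_units <= 0) abort("effect size must be positive.")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("alpha and power must be in (0, 1).")
  }
  z_a <- if (sided == "two") qnorm(1 - alpha / 2) else qnorm(1 - alpha)
  z_b <- qnorm(power)
  n_group <- ceiling(2 * (z_a + z_b)^2 / effect_sd_units^2)
  tibble(n_per_group = n_group, n_total = 2 * n_group)
}
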