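new_mwas_table <- function(tbl, method, lambda_gc, n = NA_integer_,
                           fallback = FALSE) {
  tbl <- dplyr::arrange(tbl, as.integer(.data$chr), .data$bp)
  structure(tbl, class = c("mwas_table", class(tibble())),
            method = method, lambda_gc = lambda_gc, n = n, fallback = fallback)
}

#' @export
print.mwas_table <- function(x, ...) {
  cat(sprintf("# MWAS [%s], %d probes, lambda_gc = %.3f%s\n",
              attr(x, "method"), nrow(x), attr(x, "lambda_gc"),
              if (isTRUE(attr(x, "fallback"))) " (single-component fallback)" else ""))
  NextMethod()
}

#' @export
glance.mwas_table <- function(x, ...) {
  tibble(method = attr(x, "method"), m_probes = nrow(x),
         lambda_gc = attr(x, "lambda_gc"), nobs = attr(x, "n"),
         min_p = min(x$p))
}

mwas_result_from <- function(m, b, se, p, method, n) {
  tbl <- tibble(
    chr = m$probe_annot$chr, probe_id = m$probe_annot$probe_id,
    bp = m$probe_annot$bp, gene = m$probe_annot$gene,
    orientation = m$probe_annot$orientation,
    b = unname(b), se = unname(se),
    p = unname(pmin(pmax(p, .Machine$double.xmin), 1))
  )
  new_mwas_table(tbl, method = method, lambda_gc = genomic_lambda(p = tbl$p),
                 n = n)
}

check_standardized <- function(m) {
  if (!m$scale_state %in% c("standardized", "residualized")) {
    abort("association engines expect standardized probe values.")
  }
}

#' Per-probe linear-regression MWAS
#'
#' Fits `y = w_i b_i (+ C beta) + e` for every probe by ordinary least
#' squares and reports the slope, its standard error, and a two-sided
#' t-test p-value with `n - p - 2` degrees of freedom (intercept always
#' included). This is the baseline engine that mixed-model engines are
#' compared against; it has no protection against methylome-wide
#' confounding such as cell-composition or batch structure.
#'
#' @param m A standardized [methyl_set()].
#' @param y Numeric trait (0/1 status).
#' @param C Optional covariate matrix (no intercept column needed).
#' @return An MWAS tibble (`chr, probe_id, bp, gene, orientation, b, se, p`)
#'   sorted by position, with the engine tag and genomic inflation factor
#'   as attributes.
#' @export
mwas_linear <- function(m, y, C = NULL) {
  check_standardized(m)
  W <- m$values
  n <- nrow(W)
  X <- build_fixed_design(C, n)
  p_cov <- ncol(X) - 1L
  qrX <- qr(X)
  yr <- qr.resid(qrX, y)
  Wr <- qr.resid(qrX, W)
  wtw <- colSums(Wr^2)
  if (any(wtw < 1e-12)) {
    abort("a probe is collinear with the covariates; remove it first.")
  }
  b <- colSums(Wr * yr) / wtw
  df <- n - p_cov - 2L
  rss <- sum(yr^2) - b^2 * wtw
  se <- sqrt(pmax(rss / df, 0) / wtw)
  tval <- b / se
  pv <- 2 * pt(-abs(tval), df)
  mwas_result_from(m, b, se, pv, method = if (p_cov > 0) "linear_cov" else "linear",
                   n = n)
}

#' Linear MWAS adjusted for ORM principal components
#'
#' [mwas_linear()] with the top `k` principal components of the omics
#' relationship matrix appended to the covariates — the standard
#' PC-correction for methylome-wide structure.
#'
#' @inheritParams mwas_linear
#' @param orm An `orm` object (defaults to the ORM of `m`).
#' @param k Number of components (default 10).
#' @return An MWAS tibble; method tag `"linear_pc"`.
#' @export
mwas_pc_adjusted <- function(m, y, orm = NULL, k = 10, C = NULL) {
  check_standardized(m)
  if (k == 0) {
    out <- mwas_linear(m, y, C)
    return(new_mwas_table(out, method = "linear_pc",
                          lambda_gc = attr(out, "lambda_gc"), n = attr(out, "n")))
  }
  if (is.null(orm)) orm <- compute_orm(m)
  pcs <- orm_pca(orm, k)
  out <- mwas_linear(m, y, C = cbind(C, pcs))
  new_mwas_table(out, method = "linear_pc", lambda_gc = attr(out, "lambda_gc"),
                 n = attr(out, "n"))
}

#' Mixed-linear-model omics association (single random component)
#'
#' Two-step per-probe test under `y = w_i b_i + C beta + g + e` with
#' `g ~ N(0, A sigma_o^2)`: (i) the genome-wide null model (no probe fixed
#' effect) is fitted once by REML; (ii) each probe is tested by generalized
#' least squares at the fitted variance components,
#' `b_i = w_i' V^-1 (y - C beta) / (w_i' V^-1 w_i)`, with a chi-square
#' (1 df) p-value. The tested probe is also part of the random component,
#' which costs a little power but keeps the computation to a single
#' eigendecomposition: all probes are rotated into the eigenbasis of `A`,
#' where `V` is diagonal.
#'
#' @inheritParams mwas_linear
#' @param reml Optional precomputed null-model [reml_fit()] (must have been
#'   fitted with the same `C` and the ORM of `m`).
#' @return An MWAS tibble; method tag `"moa"`.
#' @export
mwas_moa <- function(m, y, C = NULL, reml = NULL) {
  check_standardized(m)
  W <- m$values
  n <- nrow(W)
  orm <- compute_orm(m)
  if (is.null(reml)) reml <- reml_fit(y, C, list(orm))
  X <- build_fixed_design(C, n)
  resid <- y - drop(X %*% reml$beta_hat[colnames(X)])
  eg <- eigen(orm$A, symmetric = TRUE)
  d <- reml$sigma2[["orm1"]] * pmax(eg$values, 0) + reml$sigma2[["residual"]]
  Ws <- crossprod(eg$vectors, W)
  rs <- drop(crossprod(eg$vectors, resid))
  num <- colSums(Ws * (rs / d))
  den <- colSums(Ws^2 / d)
  b <- num / den
  se <- 1 / sqrt(den)
  chi2 <- (b / se)^2
  pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
  mwas_result_from(m, b, se, pv, method = "moa", n = n)
}

#' Configuration for the multi-component association engine
#'
#' @param window_bp Total exclusion window centred on the tested probe
#'   (default 100000 bp, i.e. +/- 50 kb on the same chromosome).
#' @param group_p_threshold Initial-scan p-value separating the
#'   "most-associated" probe group (fitted as its own random component)
#'   from the rest; default `0.05 / m` (set at fit time when `NULL`).
#' @param refit_variance_per_probe If `TRUE`, variance components are
#'   re-estimated by REML for every probe on its downdated group ORMs
#'   (slow exact path); default reuses the null-model components.
#' @return A list of class `moment_config`.
#' @export
moment_config <- function(window_bp = 100000, group_p_threshold = NULL,
                          refit_variance_per_probe = FALSE) {
  if (window_bp < 0) abort("window_bp must be >= 0.")
  if (!is.null(group_p_threshold) &&
      (group_p_threshold <= 0 || group_p_threshold >= 1)) {
    abort("group_p_threshold must be in (0, 1).")
  }
  structure(list(window_bp = window_bp, group_p_threshold = group_p_threshold,
                 refit_variance_per_probe = refit_variance_per_probe),
            class = "moment_config")
}

#' Multi-component MLM association excluding the target window
#'
#' Per-probe mixed-model test `y = w_i b_i + sum_j W_j u_j + e` in which
#' probes are partitioned by an initial linear scan into a
#' "most-associated" group and the remainder, each fitted as its own
#' random component so the two groups may have different effect-size
#' distributions. For every tested probe, all probes within half the
#' window on the same chromosome — including the probe itself — are
#' excluded from both random components, which removes proximal
#' contamination (a probe being tested against a component containing
#' itself or correlated neighbours).
#'
#' Variance components are estimated once from the full group ORMs under
#' the null model and reused across probes; the per-probe window exclusion
#' enters the GLS solve exactly, as a low-rank downdate of `V` at fixed
#' per-probe effect variances (`sigma_j^2 / m_j`), via the Woodbury
#' identity. When the initial scan puts no probe past the group threshold
#' the engine falls back to a single genome-wide component (the
#' single-component engine plus window exclusion), recorded in the
#' `fallback` attribute of the result.
#'
#' @inheritParams mwas_linear
#' @param cfg A [moment_config()].
#' @return An MWAS tibble; method tag `"moment"`.
#' @export
mwas_moment <- function(m, y, C = NULL, cfg = moment_config()) {
  check_standardized(m)
  W <- m$values
  n <- nrow(W)
  m_all <- ncol(W)
  thr <- cfg$group_p_threshold %||% (0.05 / m_all)

  scan <- mwas_linear(m, y, C)
  p_scan <- scan$p[match(colnames(W), scan$probe_id)]
  group <- ifelse(p_scan < thr, 1L, 2L)
  fallback <- !any(group == 1L) || !any(group == 2L)
  if (fallback) group <- rep(1L, m_all)
  group_ids <- split(colnames(W), group)

  orms <- lapply(group_ids, function(ids) compute_orm(m, probe_subset = ids))
  fit <- reml_fit(y, C, orms)
  X <- build_fixed_design(C, n)
  resid <- y - drop(X %*% fit$beta_hat[colnames(X)])

  q <- length(orms)
  sigma2 <- fit$sigma2
  # per-probe effect variance of each probe, by its group
  m_j <- vapply(orms, function(o) o$m, numeric(1))
  sig_u <- setNames(sigma2[seq_len(q)] / m_j, names(group_ids))
  d_probe <- sig_u[as.character(group)]

  V <- diag(sigma2[["residual"]], n)
  for (j in seq_len(q)) V <- V + sigma2[[j]] * orms[[j]]$A
  Vinv <- chol2inv(chol(V))
  Z <- Vinv %*% W
  Vy <- drop(Vinv %*% resid)

  annot <- m$probe_annot
  ord <- order(as.integer(annot$chr), annot$bp)
  b <- se <- rep(NA_real_, m_all)

  if (cfg$refit_variance_per_probe) {
    for (i in seq_len(m_all)) {
      excl <- window_excluded_probes(annot, annot$probe_id[i], cfg$window_bp)
      res <- moment_refit_one(m, y, C, group_ids, excl, annot$probe_id[i])
      b[i] <- res$b; se[i] <- res$se
    }
  } else {
    pos <- annot$bp
    chr <- annot$chr
    half <- cfg$window_bp / 2
    for (i in seq_len(m_all)) {
      near <- which(chr == chr[i] & abs(pos - pos[i]) <= half)
      E <- union(near, i)
      U <- W[, E, drop = FALSE]
      Zu <- Z[, E, drop = FALSE]
      S <- diag(1 / d_probe[E], length(E)) - crossprod(U, Zu)
      Sinv_Zur <- solve(S, crossprod(Zu, resid))
      Zuw <- crossprod(Zu, W[, i])
      wVr <- sum(W[, i] * Vy) + drop(crossprod(Zuw, Sinv_Zur))
      wVw <- sum(W[, i] * Z[, i]) + drop(crossprod(Zuw, solve(S, Zuw)))
      b[i] <- wVr / wVw
      se[i] <- 1 / sqrt(wVw)
    }
  }
  chi2 <- (b / se)^2
  pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
  out <- mwas_result_from(m, b, se, pv, method = "moment", n = n)
  attr(out, "fallback") <- fallback
  attr(out, "group_p_threshold") <- thr
  out
}

# Exact slow path: re-estimate variance components per probe on the
# downdated group ORMs, then GLS-test the target.
moment_refit_one <- function(m, y, C, group_ids, excl, target) {
  orms <- lapply(names(group_ids), function(g) {
    ids <- setdiff(group_ids[[g]], excl)
    if (length(ids) == 0) return(NULL)
    compute_orm(m, probe_subset = ids, group_label = g)
  })
  orms <- orms[!vapply(orms, is.null, logical(1))]
  fit <- reml_fit(y, C, orms)
  n <- length(y)
  V <- diag(fit$sigma2[["residual"]], n)
  for (j in seq_along(orms)) V <- V + fit$sigma2[[j]] * orms[[j]]$A
  Vinv <- chol2inv(chol(V))
  X <- build_fixed_design(C, n)
  resid <- y - drop(X %*% fit$beta_hat[colnames(X)])
  w <- m$values[, target]
  wV <- drop(Vinv %*% w)
  list(b = sum(wV * resid) / sum(wV * w), se = 1 / sqrt(sum(wV * w)))
}

#' Genomic inflation factor
#'
#' Median of the observed chi-square (1 df) statistics divided by the null
#' median `qchisq(0.5, 1) = 0.4549364`. Values near 1 indicate calibrated
#' tests; inflation signals confounding or polygenic signal.
#'
#' @param p P-values (converted through the inverse chi-square survival
#'   function) or
#' @param chi2 chi-square statistics directly.
#' @return The inflation factor, a single number.
#' @export
genomic_lambda <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p)) abort("supply p-values or chi-square statistics.")
    chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chi2) < 1) abort("need at least one test statistic.")
  median(chi2) / qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param m Number of tests.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (m < 1) abort("m must be >= 1.")
  alpha / m
}
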