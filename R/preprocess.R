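#' Filter probes by variability and exclusion lists
#'
#' Removes probes whose raw beta-value standard deviation falls below
#' `sd_min` (low-variance probes carry little power and inflate the
#' multiple-testing burden) and probes named in `exclude_ids` (stand-ins
#' for sex-chromosome, SNP-affected, or cross-hybridizing probe lists).
#'
#' @param m A beta-scale [methyl_set()].
#' @param sd_min Minimum raw standard deviation (default 0.02).
#' @param exclude_ids Character vector of probe ids to drop.
#' @return The filtered `methyl_set`; a tibble of per-reason removal counts
#'   is attached as attribute `"filter_counts"`.
#' @export
filter_probes <- function(m, sd_min = 0.02, exclude_ids = character(0)) {
  if (m$scale_state != "beta") abort("filter_probes() expects beta-scale values.")
  sds <- matrixStats_colSds(m$values)
  low <- sds < sd_min
  excl <- colnames(m$values) %in% exclude_ids
  keep <- !(low | excl)
  if (!any(keep)) abort("all probes removed by filtering; nothing left to analyse.")
  counts <- tibble(
    reason = c("low_sd", "exclusion_list", "kept"),
    n = c(sum(low), sum(excl & !low), sum(keep))
  )
  out <- subset_probes(m, which(keep))
  attr(out, "filter_counts") <- counts
  out
}

# column SDs with the sample (n-1) divisor, without extra dependencies
matrixStats_colSds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt((colSums(x^2) - n * mu^2) / (n - 1))
}

#' Standardize probes to mean zero, variance one
#'
#' Uses the population (divisor-n) convention so the omics relationship
#' matrix built from the result has mean diagonal exactly 1.
#'
#' @param m A [methyl_set()] with no zero-variance probes.
#' @return A `methyl_set` with `scale_state = "standardized"`.
#' @export
standardize_probes <- function(m) {
  x <- m$values
  n <- nrow(x)
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  if (any(v <= 0)) {
    bad <- colnames(x)[which(v <= 0)]
    abort(paste0("zero-variance probes (filter first): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  z <- sweep(sweep(x, 2, mu), 2, sqrt(v), `/`)
  methyl_set(z, m$probe_annot, scale_state = "standardized")
}

#' Residualize probes on sample covariates
#'
#' Replaces every probe by the residuals of an ordinary least-squares fit
#' of the probe on the chosen covariates (intercept always included;
#' categorical covariates are expanded to indicators). With an empty
#' covariate list this is mean-centering. Residuals are typically
#' re-standardized with [standardize_probes()] before association testing.
#'
#' @param m A [methyl_set()].
#' @param samples Sample tibble aligned to `m`.
#' @param covariates Character vector of column names in `samples`.
#' @return A `methyl_set` with `scale_state = "residualized"`.
#' @export
residualize_probes <- function(m, samples, covariates = character(0)) {
  samples <- align_samples(m, samples)
  C <- covariate_design(samples, covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    abort(paste0("rank-deficient covariate design; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }
  resid <- m$values - C %*% qr.coef(qrC, m$values)
  dimnames(resid) <- dimnames(m$values)
  methyl_set(resid, m$probe_annot, scale_state = "residualized")
}

# Build a fixed-effect design matrix (with intercept) from sample columns;
# character/factor columns expand to treatment-coded indicators.
covariate_design <- function(samples, covariates, intercept = TRUE) {
  samples <- as_tibble(samples)
  missing_c <- setdiff(covariates, names(samples))
  if (length(missing_c) > 0) {
    abort(paste0("covariates not in sample table: ",
                 paste(missing_c, collapse = ", ")))
  }
  if (length(covariates) == 0) {
    C <- matrix(1, nrow(samples), 1, dimnames = list(NULL, "(Intercept)"))
    return(if (intercept) C else C[, 0, drop = FALSE])
  }
  # always build with an intercept so factors get treatment coding, then
  # drop the constant column if the caller supplies their own
  fml <- stats::reformulate(sprintf("`%s`", covariates), intercept = TRUE)
  df <- as.data.frame(samples[, covariates, drop = FALSE])
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  C <- stats::model.matrix(fml, df)
  if (intercept) C else C[, -1, drop = FALSE]
}

#' Estimate blood cell-type proportions by reference-based deconvolution
#'
#' For each individual, solves the constrained least-squares projection
#' `min || x - R' pi ||^2` subject to `pi >= 0` and `sum(pi) <= 1`, where
#' `R` holds the mean beta values of purified cell types over the signature
#' probes shared between reference and cohort. Any mass not assigned to a
#' cell type is unexplained signal.
#'
#' @param m A beta-scale [methyl_set()].
#' @param reference A `cell_reference` (cell types x probes).
#' @return Tibble: `sample_id` plus one proportion column per cell type.
#' @export
estimate_ctp <- function(m, reference) {
  if (m$scale_state != "beta") abort("estimate_ctp() expects beta-scale values.")
  shared <- intersect(colnames(reference), colnames(m$values))
  K <- nrow(reference)
  if (length(shared) < K) {
    abort(sprintf(
      "insufficient signature overlap: %d shared probes for %d cell types.",
      length(shared), K))
  }
  R <- t(unclass(reference)[, shared, drop = FALSE])   # probes x K
  X <- m$values[, shared, drop = FALSE]
  pen <- 1e4 * sqrt(mean(R^2) * nrow(R))               # sum-constraint penalty row
  prop <- t(apply(X, 1, function(x) {
    pi_hat <- pracma::lsqnonneg(R, x)$x
    if (sum(pi_hat) > 1 + 1e-8) {
      # boundary case: re-solve with the sum pinned to 1
      pi_hat <- pracma::lsqnonneg(rbind(R, rep(pen, K)), c(x, pen))$x
    }
    pi_hat
  }))
  colnames(prop) <- rownames(reference)
  dplyr::bind_cols(tibble(sample_id = sample_ids(m)), as_tibble(prop))
}
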