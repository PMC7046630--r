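#' Methylation data container
#'
#' A `methyl_set` bundles an individuals-by-probes numeric matrix with its
#' probe annotation and a scale state. The matrix is the `W` of the mixed
#' linear model once standardized; rows are individuals, columns are probes.
#'
#' @param values Numeric matrix, individuals x probes, with dimnames
#'   (sample ids, probe ids).
#' @param probe_annot Tibble with columns `probe_id`, `chr` (character,
#'   "1".."22"), `bp` (1-based integer position), `gene`, `orientation`
#'   ("F"/"R"), one row per matrix column, in column order.
#' @param scale_state One of `"beta"`, `"standardized"`, `"residualized"`.
#'   Beta values must lie in `[0, 1]`; standardized values have per-probe
#'   mean 0 and population variance 1.
#'
#' @return An object of class `methyl_set`.
#' @export
methyl_set <- function(values, probe_annot,
                       scale_state = c("beta", "standardized", "residualized")) {
  scale_state <- match.arg(scale_state)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (individuals x probes).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry sample ids (rownames) and probe ids (colnames).")
  }
  probe_annot <- as_tibble(probe_annot)
  required <- c("probe_id", "chr", "bp", "gene", "orientation")
  missing_cols <- setdiff(required, names(probe_annot))
  if (length(missing_cols) > 0) {
    abort(paste0("`probe_annot` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(probe_annot) != ncol(values)) {
    abort("`probe_annot` must have one row per probe (matrix column).")
  }
  if (!identical(probe_annot$probe_id, colnames(values))) {
    abort("`probe_annot$probe_id` must match colnames(values) in order.")
  }
  if (anyDuplicated(probe_annot$probe_id) > 0) {
    abort("duplicate probe ids in annotation.")
  }
  if (anyDuplicated(rownames(values)) > 0) {
    abort("duplicate sample ids in matrix.")
  }
  if (anyNA(values)) {
    abort("missing methylation values are not supported; impute or drop upstream.")
  }
  if (scale_state == "beta" && (min(values) < 0 || max(values) > 1)) {
    abort("beta-scale values must lie in [0, 1].")
  }
  structure(
    list(values = values,
         probe_annot = probe_annot,
         scale_state = scale_state),
    class = "methyl_set"
  )
}

#' @export
print.methyl_set <- function(x, ...) {
  cat(sprintf("<methyl_set> %d individuals x %d probes [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale_state))
  invisible(x)
}

#' @export
dim.methyl_set <- function(x) dim(x$values)

#' Number of probes / samples in a methyl_set
#' @param x A `methyl_set`.
#' @return Integer count.
#' @export
n_probes <- function(x) ncol(x$values)

#' @rdname n_probes
#' @export
n_samples <- function(x) nrow(x$values)

#' Sample identifiers of a methyl_set
#' @param x A `methyl_set`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' Subset a methyl_set by probes (and optionally samples)
#'
#' @param x A `methyl_set`.
#' @param probes Character vector of probe ids or logical/integer index.
#' @param samples Optional sample ids or index.
#' @return A `methyl_set` restricted to the selection, annotation aligned.
#' @export
subset_probes <- function(x, probes, samples = NULL) {
  if (is.character(probes)) {
    missing_p <- setdiff(probes, colnames(x$values))
    if (length(missing_p) > 0) {
      abort(paste0("probes not present: ", paste(head(missing_p, 5), collapse = ", ")))
    }
    idx <- match(probes, colnames(x$values))
  } else {
    idx <- seq_len(ncol(x$values))[probes]
  }
  vals <- x$values[, idx, drop = FALSE]
  if (!is.null(samples)) vals <- vals[samples, , drop = FALSE]
  methyl_set(vals, x$probe_annot[idx, ], scale_state = x$scale_state)
}

#' Check that a sample table aligns with a methyl_set
#'
#' @param m A `methyl_set`.
#' @param samples Tibble with a `sample_id` column (plus status/covariates).
#' @return Invisibly, `samples` reordered to the matrix rows.
#' @export
align_samples <- function(m, samples) {
  samples <- as_tibble(samples)
  if (!"sample_id" %in% names(samples)) abort("sample table needs a `sample_id` column.")
  ids <- sample_ids(m)
  missing_ids <- setdiff(ids, samples$sample_id)
  extra_ids <- setdiff(samples$sample_id, ids)
  if (length(missing_ids) > 0 || length(extra_ids) > 0) {
    abort(paste0(
      "sample table does not align with methylation matrix.",
      if (length(missing_ids) > 0)
        paste0(" Missing: ", paste(head(missing_ids, 5), collapse = ", "), ".") else "",
      if (length(extra_ids) > 0)
        paste0(" Unmatched: ", paste(head(extra_ids, 5), collapse = ", "), ".") else ""
    ))
  }
  samples[match(ids, samples$sample_id), ]
}
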