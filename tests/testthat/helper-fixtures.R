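# Small in-code fixtures shared across test files.

# iid-normal standardized methyl_set with configurable probe spacing
make_white_methyl <- function(n, m, seed = 1, bp_gap = 2e5, chr = "1") {
  set.seed(seed)
  W <- matrix(rnorm(n * m), n, m)
  W <- sweep(W, 2, colMeans(W))
  W <- sweep(W, 2, sqrt(colMeans(W^2)), `/`)
  dimnames(W) <- list(sprintf("s%03d", seq_len(n)), sprintf("cg%05d", seq_len(m)))
  annot <- tibble::tibble(
    probe_id = colnames(W), chr = rep(chr, m),
    bp = as.integer(seq_len(m) * bp_gap), gene = "g", orientation = "F"
  )
  methyl_set(W, annot, scale_state = "standardized")
}

# beta-scale methyl_set from explicit values
make_beta_methyl <- function(vals, bp = NULL, chr = NULL) {
  n <- nrow(vals); m <- ncol(vals)
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(vals))) colnames(vals) <- sprintf("cg%05d", seq_len(m))
  annot <- tibble::tibble(
    probe_id = colnames(vals),
    chr = chr %||% rep("1", m),
    bp = as.integer(bp %||% (seq_len(m) * 1e5)),
    gene = "g", orientation = "F"
  )
  methyl_set(vals, annot, scale_state = "beta")
}

`%||%` <- rlang::`%||%`
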