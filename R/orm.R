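new_orm <- function(A, m, probe_ids = NULL, group_label = NULL) {
  structure(list(A = A, m = m, probe_ids = probe_ids, group_label = group_label),
            class = "orm")
}

#' @export
print.orm <- function(x, ...) {
  cat(sprintf("<orm> %d x %d from %d probes%s\n", nrow(x$A), ncol(x$A), x$m,
              if (!is.null(x$group_label)) paste0(" [", x$group_label, "]") else ""))
  invisible(x)
}

#' Compute the omics relationship matrix A = WW'/m
#'
#' The methylation analogue of a genomic relationship matrix: pairwise
#' individual similarity over standardized probe values. With
#' population-standardized probes the diagonal averages exactly 1.
#'
#' @param m A standardized (or residualized-then-restandardized)
#'   [methyl_set()].
#' @param probe_subset Optional probe ids (or index) restricting the matrix.
#' @param group_label Optional label carried on the result.
#' @return An object of class `orm` with fields `A` (n x n), `m` (probes
#'   used) and `probe_ids`.
#' @export
compute_orm <- function(m, probe_subset = NULL, group_label = NULL) {
  if (!m$scale_state %in% c("standardized", "residualized")) {
    abort("compute_orm() expects standardized values; run standardize_probes().")
  }
  W <- m$values
  if (!is.null(probe_subset)) {
    if (length(probe_subset) == 0) abort("empty probe subset.")
    W <- subset_probes(m, probe_subset)$values
  }
  A <- tcrossprod(W) / ncol(W)
  new_orm(A, m = ncol(W), probe_ids = colnames(W), group_label = group_label)
}

#' Principal components of an omics relationship matrix
#'
#' Top-k eigenvectors scaled by the square root of their eigenvalues,
#' in descending eigenvalue order. The sign of each component is fixed so
#' its largest-magnitude loading is positive.
#'
#' @param orm An `orm` object.
#' @param k Number of components (<= n).
#' @return An n x k matrix of component scores (rownames = sample ids).
#' @export
orm_pca <- function(orm, k) {
  n <- nrow(orm$A)
  if (k > n) abort("k exceeds the number of individuals.")
  if (k == 0) return(matrix(0, n, 0, dimnames = list(rownames(orm$A), NULL)))
  eg <- eigen(orm$A, symmetric = TRUE)
  vals <- pmax(eg$values[seq_len(k)], 0)
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(orm$A), paste0("PC", seq_len(k)))
  scores
}

# Probes excluded around a target: same chromosome, within half the window
# on either side (inclusive), plus the target itself.
window_excluded_probes <- function(probe_annot, target_probe, window_bp) {
  t_row <- probe_annot[probe_annot$probe_id == target_probe, ]
  if (nrow(t_row) != 1) abort(sprintf("target probe %s not found.", target_probe))
  same_chr <- probe_annot$chr == t_row$chr
  near <- same_chr & abs(probe_annot$bp - t_row$bp) <= window_bp / 2
  probe_annot$probe_id[near | probe_annot$probe_id == target_probe]
}

#' Group ORMs with a proximal window excluded around a target probe
#'
#' For each probe group, rebuilds the group ORM with every probe on the
#' target's chromosome within `window_bp / 2` base pairs of the target
#' (and the target itself) removed, by downdating the precomputed full
#' group ORM: the excluded probes' outer products are subtracted and the
#' matrix rescaled to the reduced probe count. Exclusion applies to every
#' group. Used by the multi-component association engine to avoid testing
#' a probe against a random component that contains itself or its
#' neighbours (proximal contamination).
#'
#' @param m A standardized [methyl_set()] (positions in its annotation).
#' @param groups Named integer/character vector mapping probe id to group.
#' @param target_probe Probe id being tested.
#' @param window_bp Total window width in bp centred on the target
#'   (default 100000, i.e. +/- 50 kb).
#' @param full_orms Optional precomputed list of full per-group `orm`s
#'   (avoids recomputation across targets).
#' @return Named list of downdated `orm` objects, one per group.
#' @export
windowed_group_orm <- function(m, groups, target_probe, window_bp = 100000,
                               full_orms = NULL) {
  if (window_bp < 0) abort("window_bp must be >= 0.")
  probe_ids <- colnames(m$values)
  if (!all(names(groups) %in% probe_ids) || is.null(names(groups))) {
    abort("`groups` must be named by probe id, all present in the matrix.")
  }
  excl <- window_excluded_probes(m$probe_annot, target_probe, window_bp)
  levels_g <- sort(unique(groups))
  if (is.null(full_orms)) {
    full_orms <- lapply(levels_g, function(g) {
      compute_orm(m, probe_subset = names(groups)[groups == g],
                  group_label = as.character(g))
    })
    names(full_orms) <- as.character(levels_g)
  }
  out <- lapply(as.character(levels_g), function(g) {
    orm_g <- full_orms[[g]]
    drop_ids <- intersect(orm_g$probe_ids, excl)
    m_new <- orm_g$m - length(drop_ids)
    if (m_new < 1) {
      abort(sprintf("group %s has no probes left after window exclusion.", g),
            class = "methylmlm_degenerate_group")
    }
    if (length(drop_ids) == 0) return(orm_g)
    W_ex <- m$values[, drop_ids, drop = FALSE]
    A_new <- (orm_g$m * orm_g$A - tcrossprod(W_ex)) / m_new
    new_orm(A_new, m = m_new, probe_ids = setdiff(orm_g$probe_ids, drop_ids),
            group_label = orm_g$group_label)
  })
  names(out) <- as.character(levels_g)
  out
}
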