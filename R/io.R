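#' Read a methylation matrix with probe and sample annotation
#'
#' The on-disk layout follows the omics-association text convention:
#' the matrix file is probes-as-rows, individuals-as-columns TSV with a
#' `probe_id` first column; the probe annotation file has columns
#' `chr probe_id bp gene orientation`; the sample file is a TSV with a
#' `sample_id` column plus status/covariates. Values round-trip at full
#' double precision.
#'
#' @param matrix_path,probe_annot_path,sample_path File paths.
#' @param scale_state Scale of the stored values (default `"beta"`).
#' @return A list with `methyl` (a [methyl_set()]) and `samples` (tibble,
#'   aligned to the matrix rows).
#' @export
read_methylation <- function(matrix_path, probe_annot_path, sample_path,
                             scale_state = "beta") {
  mat_dt <- data.table::fread(matrix_path, sep = "\t", header = TRUE,
                              colClasses = list(character = 1))
  probe_ids <- mat_dt[[1]]
  vals <- as.matrix(mat_dt[, -1])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(mat_dt[, -1], is.numeric, logical(1)))[1]
    abort(sprintf("non-numeric methylation values in column %d of %s.",
                  bad + 1L, matrix_path))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value at probe row %d, sample column %d in %s.",
                  idx[1], idx[2], matrix_path))
  }
  rownames(vals) <- probe_ids
  annot <- read_probe_annot(probe_annot_path)
  if (anyDuplicated(annot$probe_id) > 0) {
    abort("duplicate probe_id in probe annotation file.")
  }
  missing_p <- setdiff(probe_ids, annot$probe_id)
  if (length(missing_p) > 0) {
    abort(paste0("probes missing from annotation: ",
                 paste(head(missing_p, 5), collapse = ", ")))
  }
  annot <- annot[match(probe_ids, annot$probe_id), ]
  samples <- as_tibble(data.table::fread(sample_path, sep = "\t", header = TRUE,
                                         colClasses = list(character = "sample_id")))
  m <- methyl_set(t(vals), annot, scale_state = scale_state)
  samples <- align_samples(m, samples)
  list(methyl = m, samples = samples)
}

read_probe_annot <- function(path) {
  annot <- as_tibble(data.table::fread(
    path, sep = "\t", header = TRUE,
    colClasses = list(character = c("chr", "probe_id", "gene", "orientation"))))
  needed <- c("chr", "probe_id", "bp", "gene", "orientation")
  if (!all(needed %in% names(annot))) {
    abort(paste0("probe annotation needs columns: ", paste(needed, collapse = ", ")))
  }
  annot[, c("probe_id", "chr", "bp", "gene", "orientation")]
}

#' Write a methylation matrix with its annotation files
#'
#' @param m A [methyl_set()].
#' @param samples Sample tibble aligned to `m`.
#' @param matrix_path,probe_annot_path,sample_path Output file paths.
#' @return Invisibly, the three paths.
#' @export
write_methylation <- function(m, samples, matrix_path, probe_annot_path,
                              sample_path) {
  vals <- t(m$values)
  dt <- data.table::data.table(probe_id = rownames(vals))
  # %.17g guarantees bit-exact round trip of doubles through text
  num <- data.table::as.data.table(apply(vals, 2, sprintf, fmt = "%.17g"))
  dt <- cbind(dt, num)
  data.table::fwrite(dt, matrix_path, sep = "\t", quote = FALSE)
  annot <- m$probe_annot[, c("chr", "probe_id", "bp", "gene", "orientation")]
  data.table::fwrite(annot, probe_annot_path, sep = "\t")
  data.table::fwrite(align_samples(m, samples), sample_path, sep = "\t")
  invisible(c(matrix_path, probe_annot_path, sample_path))
}

#' Write an MWAS result table
#'
#' Fixed column order `Chr Probe bp Gene Orientation b se p`, rows sorted by
#' chromosome then position, p-values in scientific notation; the engine tag
#' and genomic inflation factor are stored in `#`-prefixed header lines.
#'
#' @param table An MWAS result tibble (see [mwas_linear()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mwas <- function(table, path) {
  tab <- dplyr::arrange(table, as.integer(.data$chr), .data$bp)
  hdr <- c(
    sprintf("# method: %s", attr(table, "method") %||% "unknown"),
    sprintf("# lambda_gc: %s", format(attr(table, "lambda_gc") %||% NA_real_,
                                      digits = 10))
  )
  out <- data.table::data.table(
    Chr = tab$chr, Probe = tab$probe_id, bp = tab$bp, Gene = tab$gene,
    Orientation = tab$orientation,
    b = formatC(tab$b, digits = 10, format = "g"),
    se = formatC(tab$se, digits = 10, format = "g"),
    p = formatC(tab$p, digits = 6, format = "e")
  )
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read an MWAS result table written by [write_mwas()]
#'
#' @param path File path.
#' @return An MWAS result tibble with `method` and `lambda_gc` attributes.
#' @export
read_mwas <- function(path) {
  hdr <- readLines(path, n = 2L)
  method <- sub("^# method: ", "", hdr[1])
  lambda <- as.numeric(sub("^# lambda_gc: ", "", hdr[2]))
  dt <- data.table::fread(path, sep = "\t", skip = 2L, header = TRUE,
                          colClasses = list(character = c("Chr", "Probe", "Gene",
                                                          "Orientation")))
  out <- tibble(
    chr = dt$Chr, probe_id = dt$Probe, bp = dt$bp, gene = dt$Gene,
    orientation = dt$Orientation, b = as.numeric(dt$b),
    se = as.numeric(dt$se), p = as.numeric(dt$p)
  )
  new_mwas_table(out, method = method, lambda_gc = lambda)
}

#' Write / read an omics relationship matrix in GRM-style text
#'
#' `<prefix>.orm.txt` holds lower-triangle triplets
#' `(i, j, m_used, A[i, j])`; `<prefix>.orm.id` holds one sample id per line.
#'
#' @param orm An `orm` object from [compute_orm()].
#' @param prefix Output path prefix.
#' @return Invisibly, the prefix.
#' @export
write_orm <- function(orm, prefix) {
  A <- orm$A
  n <- nrow(A)
  idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dt <- data.table::data.table(
    i = idx[, 1], j = idx[, 2], m = orm$m,
    value = A[idx]
  )
  data.table::fwrite(dt, paste0(prefix, ".orm.txt"), sep = "\t", col.names = FALSE)
  writeLines(rownames(A), paste0(prefix, ".orm.id"))
  invisible(prefix)
}

#' @rdname write_orm
#' @export
read_orm <- function(prefix) {
  ids <- readLines(paste0(prefix, ".orm.id"))
  dt <- data.table::fread(paste0(prefix, ".orm.txt"), sep = "\t", header = FALSE)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(dt$V1, dt$V2)] <- dt$V4
  A[cbind(dt$V2, dt$V1)] <- dt$V4
  new_orm(A, m = dt$V3[1], probe_ids = NULL)
}
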