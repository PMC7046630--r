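#' Manhattan plot of an MWAS result
#'
#' @param object An MWAS tibble.
#' @param sig Genome-wide significance line (default the Bonferroni
#'   threshold for the table's probe count).
#' @param suggestive Suggestive line (default 1e-5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mwas_table <- function(object, sig = NULL, suggestive = 1e-5, ...) {
  sig <- sig %||% bonferroni_threshold(nrow(object))
  df <- dplyr::arrange(tibble::as_tibble(object), as.integer(.data$chr), .data$bp)
  df$pos <- seq_len(nrow(df))
  df$chr_f <- factor(as.integer(df$chr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                   colour = .data$chr_f)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = rep(c("grey30", "steelblue"), 11)[seq_along(unique(df$chr_f))]) +
    ggplot2::geom_hline(yintercept = -log10(sig), colour = "darkblue") +
    ggplot2::geom_hline(yintercept = -log10(suggestive), colour = "skyblue",
                        linetype = "dashed") +
    ggplot2::labs(x = "probe (genome order)", y = expression(-log[10](p)),
                  title = sprintf("MWAS [%s], lambda = %.2f",
                                  attr(object, "method"),
                                  attr(object, "lambda_gc"))) +
    ggplot2::theme_minimal()
}

#' QQ plot of MWAS p-values
#'
#' @param mwas An MWAS tibble, or a named list of them for overlaying
#'   engines.
#' @return A ggplot object annotated with each engine's inflation factor.
#' @export
plot_qq <- function(mwas) {
  if (inherits(mwas, "mwas_table")) mwas <- list(mwas)
  df <- dplyr::bind_rows(lapply(mwas, function(tab) {
    p <- sort(tab$p)
    tibble(expected = -log10(stats::ppoints(length(p))), observed = -log10(p),
           engine = sprintf("%s (lambda = %.2f)", attr(tab, "method"),
                            attr(tab, "lambda_gc")))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$engine)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Boxplots of estimated cell proportions by case-control status
#'
#' @param ctp Tibble from [estimate_ctp()].
#' @param status 0/1 status aligned to `ctp` rows.
#' @return A ggplot object (proportions shown in percent).
#' @export
plot_ctp <- function(ctp, status) {
  df <- ctp
  df$status <- factor(ifelse(status == 1, "case", "control"))
  long <- tidyr::pivot_longer(df, cols = -c("sample_id", "status"),
                              names_to = "cell_type", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type,
                                     y = 100 * .data$proportion,
                                     fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "predicted cell proportion (%)") +
    ggplot2::theme_minimal()
}

#' Bar chart of classification AUCs with confidence intervals
#'
#' @param auc_tab Tibble of [classify_scores()] rows with a `method`
#'   column (e.g. the `auc` table of [run_pipeline()]); when several rows
#'   share a method, the best AUC per method is shown.
#' @return A ggplot object.
#' @export
plot_auc <- function(auc_tab) {
  best <- auc_tab |>
    dplyr::group_by(.data$method) |>
    dplyr::slice_max(.data$auc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(best, ggplot2::aes(x = stats::reorder(.data$method, .data$auc),
                                     y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(x = NULL, y = "AUC (out-of-sample)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
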