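#' Quantile-quantile plot of GWAS p-values
#'
#' Observed versus expected -log10 p-values under the uniform null, with the
#' genomic inflation factor in the subtitle.
#'
#' @param gwas Tibble with a `p` column (e.g. from [run_gwas()]), or a bare
#'   p-value vector.
#' @return A ggplot object.
#' @export
plot_qq <- function(gwas) {
  p <- if (is.data.frame(gwas)) gwas$p else gwas
  p <- sort(p[!is.na(p)])
  df <- tibble::tibble(expected = -log10(stats::ppoints(length(p))),
                       observed = -log10(p))
  lam <- if (length(p) >= 100) genomic_inflation(p) else NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = if (!is.na(lam))
                    sprintf("lambda = %.3f", lam)) +
    ggplot2::theme_minimal()
}

#' Manhattan plot
#'
#' @param gwas Tibble with `chr`, `pos`, `p` columns.
#' @param threshold Optional horizontal significance line (p-value scale),
#'   e.g. [metabolome_threshold()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(gwas, threshold = NULL) {
  df <- dplyr::filter(gwas, !is.na(.data$p))
  df <- dplyr::arrange(df, .data$chr, .data$pos)
  df$index <- seq_len(nrow(df))
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$index, -log10(.data$p),
                                        colour = factor(.data$chr %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "variant index (by position)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    g <- g + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 colour = "red", linetype = 2)
  }
  g
}

#' Plot a spectrum with its fitted peak model
#'
#' @param s Spectrum tibble.
#' @param peaks Optional fitted peaks tibble (from [deconvolute()]); drawn
#'   as the reconstructed sum.
#' @return A ggplot object (ppm axis reversed, NMR convention).
#' @export
plot_spectrum <- function(s, peaks = NULL) {
  g <- ggplot2::ggplot(s, ggplot2::aes(.data$ppm, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    fitdf <- tibble::tibble(ppm = s$ppm, intensity = sum_peaks(s$ppm, peaks))
    g <- g + ggplot2::geom_line(data = fitdf, colour = "red",
                                linewidth = 0.3, linetype = 2)
  }
  g
}

#' Heritability / household-effect bar chart
#'
#' Machine twin of a per-metabolite variance-decomposition figure: stacked
#' h2 and c2 fractions per trait.
#'
#' @param fits Tibble with columns `trait`, `h2`, `c2` (e.g. built by
#'   row-binding [tidy.reml_fit()] output).
#' @return A ggplot object.
#' @export
plot_heritability <- function(fits) {
  long <- tidyr::pivot_longer(fits[c("trait", "h2", "c2")],
                              c("h2", "c2"), names_to = "component",
                              values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(.data$trait, .data$fraction,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(h2 = "steelblue",
                                          c2 = "goldenrod")) +
    ggplot2::labs(x = NULL, y = "fraction of trait variance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
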