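#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_step geom_errorbar
#'   geom_abline geom_segment geom_vline facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a karyotype as per-chromosome coverage segments
#'
#' Called segments drawn in haploid-unit coordinates (mean normalised
#' coverage divided by the haploid unit) with the integer copy-number call
#' overlaid, one facet per chromosome; copy-number steps inside a facet
#' mark hybrid-chromosome breakpoints.
#'
#' @param object A `"karyotype"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.karyotype <- function(object, ...) {
  segs <- object$segments
  ggplot(segs) +
    geom_segment(aes(x = .data$start / 1e3, xend = .data$end / 1e3,
                     y = .data$mean / object$unit,
                     yend = .data$mean / object$unit),
                 linewidth = 0.8, colour = "grey40") +
    geom_segment(aes(x = .data$start / 1e3, xend = .data$end / 1e3,
                     y = .data$cn, yend = .data$cn),
                 linewidth = 0.6, colour = "firebrick") +
    facet_wrap(~chrom) +
    labs(x = "position (kb)", y = "copy number (coverage / haploid unit)") +
    theme_minimal()
}

#' Plot a dosage regression
#'
#' Per-category mean allele log2 fold change (point size = number of
#' pairs, error bars = SEM) against log2 copy-number ratio, with the
#' weighted regression line and the identity slope for reference.
#'
#' @param object A `"dosage_regression"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dosage_regression <- function(object, ...) {
  cats <- object$categories
  ggplot(cats, aes(x = .data$log2_ratio, y = .data$mean)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.05) +
    geom_point(aes(size = .data$n)) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "firebrick") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "log2 copy-number ratio", y = "mean allele log2 fold change",
         size = "pairs",
         title = sprintf("slope = %.2f, R² = %.2f", object$slope,
                         object$r_squared)) +
    theme_minimal()
}

#' Volcano-style plot of a DE result
#'
#' @param de DE tibble with `log2fc`, `padj`, `status` (e.g. [run_de()]).
#' @param lfc_min,fdr Thresholds drawn as guide lines.
#' @return A ggplot.
#' @export
plot_de_volcano <- function(de, lfc_min = 1, fdr = 0.05) {
  ggplot(dplyr::filter(de, !is.na(.data$padj)),
         aes(x = .data$log2fc, y = -log10(.data$padj),
             colour = .data$status)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dashed") +
    labs(x = "log2 fold change", y = "-log10 adjusted p") +
    theme_minimal()
}
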