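# ggplot2 views of the main result types.

#' Plot normalized regional coverage by genotype
#'
#' One panel per region; points are samples, crossbars the genotype
#' means - the standard view for judging a genotype-dosage coverage
#' effect region by region.
#'
#' @param coverage Tibble from [quantify_cohort()] (needs `name`,
#'   `normalized`, `genotype`).
#' @param regions Optional character vector selecting/ordering regions.
#' @return A ggplot object.
#' @export
plot_region_coverage <- function(coverage, regions = NULL) {
  df <- coverage
  if (!is.null(regions)) {
    df <- filter(df, .data$name %in% regions)
    df$name <- factor(df$name, levels = regions)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$normalized)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 1.6,
                         ggplot2::aes(colour = .data$genotype)) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "rs genotype", y = "coverage per million mapped reads") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' @describeIn ols_dosage Scatter of the fitted dosage regression.
#' @param object A `dosage_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.dosage_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$y)) +
    ggplot2::geom_jitter(width = 0.05, height = 0, alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("risk-allele dosage (%s coding)", object$grouping),
      y = "outcome",
      subtitle = sprintf("beta = %.3g, p = %.3g, r2 = %.3g",
                         object$slope, object$p, object$r2)
    ) +
    ggplot2::theme_bw()
}

#' Plot the branchpoint search window
#'
#' Candidate adenosines by acceptor-side offset with their consensus
#' scores; the variant position is highlighted. The x axis is reversed so
#' the 3' splice site sits on the right, matching how acceptor-side
#' windows are usually drawn.
#'
#' @param call A `splice_call` from [splice_scan()].
#' @return A ggplot object.
#' @export
plot_branchpoint_window <- function(call) {
  df <- tidy(call)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$offset, yend = 0,
                                       colour = .data$is_variant_site),
                          linewidth = 1.2) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "offset upstream of the 3' splice site (nt)",
                  y = "branchpoint consensus score") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}
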