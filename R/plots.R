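#' Manhattan-style plot of an association scan
#'
#' Plots -log10(P) along the chromosome with the significance and suggestive
#' thresholds, faceted by genotype format when the table covers both, and
#' the spike spans marked when given.
#'
#' @param assoc An [assoc_scan()] tibble (one or both formats stacked).
#' @param spikes Optional [aggregate_spikes()] tibble for span shading.
#' @param significance,suggestive Threshold lines (defaults 5e-8 / 5e-7).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(assoc, spikes = NULL, significance = 5e-8,
                           suggestive = 5e-7) {
  dat <- assoc[!is.na(assoc$p), , drop = FALSE]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos / 1e6,
                                         y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$typed), size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(significance),
                        linetype = "solid", colour = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(suggestive),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(P))),
                  colour = "typed") +
    ggplot2::theme_minimal()
  if (length(unique(dat$format)) > 1L) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$format))
  }
  if (!is.null(spikes) && nrow(spikes) > 0L) {
    p <- p + ggplot2::geom_vline(
      data = tibble::tibble(edge = c(spikes$start, spikes$end) / 1e6),
      ggplot2::aes(xintercept = .data$edge),
      colour = "steelblue", alpha = 0.5
    )
  }
  p
}

#' @describeIn run_midrange_filter Spike-decision plot: each spike's minimum
#'   vs maximum member quality, split by filter case, discarded spikes
#'   hollow; dashed lines mark the two thresholds.
#' @param object A `midrange_filter` object.
#' @export
autoplot.midrange_filter <- function(object, ...) {
  d <- object$decisions
  d <- d[!is.na(d$q_min), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q_min, y = .data$q_max,
                                  shape = .data$verdict,
                                  colour = .data$case)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(keep = 16, discard = 1)) +
    ggplot2::geom_vline(xintercept = object$config$lower,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$config$upper,
                        linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "minimum member quality", y = "maximum member quality",
      title = sprintf("Midrange Filter decisions (%s, %s over groups)",
                      object$config$measure, object$config$group_combine)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn roc_quality ROC curve plot with the AUC in the title.
#' @param object A `quality_roc` object.
#' @param ... Unused.
#' @export
autoplot.quality_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "1 - specificity (true associations discarded)",
      y = "sensitivity (false associations discarded)",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}
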