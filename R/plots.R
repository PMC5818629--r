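utils::globalVariables(c(
  "tissue", "bmd", "bmdl", "bmdu", "group",
  "bmd_x", "bmd_y", "bmdl_x", "bmdu_x", "bmdl_y", "bmdu_y"
))

#' Forest plot of BMD confidence intervals
#'
#' The customary sensitivity-ranking display: one horizontal BMDL-BMDU bar
#' per tissue on a log10 dose axis, ordered by the geometric midpoint of
#' the interval (most sensitive tissue at the top).
#'
#' @param ranking a [rank_tissues()] result.
#' @return a ggplot object.
#' @export
plot_bmd_forest <- function(ranking) {
  stopifnot(inherits(ranking, "bmd_ranking"))
  tab <- ranking$table
  tab$tissue <- factor(tab$tissue, levels = rev(tab$tissue))
  ggplot2::ggplot(tab, ggplot2::aes(y = tissue)) +
    ggplot2::geom_segment(ggplot2::aes(x = bmdl, xend = bmdu, yend = tissue,
                                       colour = factor(group)),
                          linewidth = 2, lineend = "round") +
    ggplot2::geom_point(ggplot2::aes(x = bmd), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "BMD and CI (log scale)", y = NULL, colour = "CI group",
      title = sprintf("BMD sensitivity ranking: %s", ranking$endpoint)
    ) +
    ggplot2::theme_minimal()
}

#' Double-log proportionality plot with the unity-slope line
#'
#' Tissue-matched BMDs of two endpoints plotted against each other on
#' log10 axes, with CI whiskers in both directions and the fitted
#' unity-slope line.
#'
#' @param prop a [proportionality()] result.
#' @return a ggplot object.
#' @export
plot_proportionality <- function(prop) {
  stopifnot(inherits(prop, "bmd_proportionality"))
  p <- prop$pairs
  ggplot2::ggplot(p, ggplot2::aes(x = bmd_x, y = bmd_y)) +
    ggplot2::geom_segment(ggplot2::aes(x = bmd_x, xend = bmd_x,
                                       y = bmdl_y, yend = bmdu_y),
                          colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = bmdl_x, xend = bmdu_x,
                                       y = bmd_y, yend = bmd_y),
                          colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = prop$log10_offset,
                         linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = tissue), vjust = -0.8, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "BMD, endpoint x (log scale)", y = "BMD, endpoint y (log scale)",
      title = sprintf("Unity-slope fit: constant = %.3g (%s)",
                      prop$proportionality_constant,
                      if (prop$unity_adequate) "unity adequate"
                      else "unity rejected")
    ) +
    ggplot2::theme_minimal()
}
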