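#' Stacked-bar decomposition of wall hydraulic resistance
#'
#' Group-mean medial and intimal resistances stacked per condition,
#' mirroring the standard series-resistance presentation.
#'
#' @param records Data frame with columns `condition`, `r_med`, `r_int`
#'   (e.g. a [run_pipeline()] results table or
#'   [decompose_resistance()] output bound to a condition column).
#' @return A ggplot object.
#' @export
plot_resistance_decomposition <- function(records) {
  stopifnot(all(c("condition", "r_med", "r_int") %in% names(records)))
  agg <- stats::aggregate(cbind(r_med, r_int) ~ condition, data = records,
                          FUN = mean)
  long <- rbind(
    data.frame(condition = agg$condition, layer = "media",
               resistance = agg$r_med),
    data.frame(condition = agg$condition, layer = "intima",
               resistance = agg$r_int))
  long$layer <- factor(long$layer, levels = c("intima", "media"))
  ggplot2::ggplot(long, ggplot2::aes(x = condition,
                                     y = resistance,
                                     fill = layer)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "hydraulic resistance (Pa s / m)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Aspect-ratio histogram of segmented cells
#'
#' The fixed 50-bin histogram over AR in \[0, 1\] with the median marked;
#' contraction skews the distribution toward zero.
#'
#' @param seg A [segment_smcs()] result.
#' @return A ggplot object.
#' @export
plot_ar_histogram <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  h <- seg$histogram
  h$mid <- (h$bin_left + h$bin_right) / 2
  ggplot2::ggplot(h, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col(width = 0.02) +
    ggplot2::geom_vline(xintercept = seg$median_ar, linetype = "dashed") +
    ggplot2::labs(x = "aspect ratio (minor / major)", y = "cells") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("condition", "resistance", "layer", "mid", "count",
                         "r_med", "r_int"))
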