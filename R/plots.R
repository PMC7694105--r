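# Base-graphics report figures.

#' Somatochart scatter plot
#'
#' Plots somatotypes on the standard somatochart plane
#' (`x = ecto - endo`, `y = 2 meso - (endo + ecto)`), with the three
#' component poles labelled and the origin (the central somatotype) marked.
#'
#' @param endomorphy,mesomorphy,ectomorphy rating vectors, or a data frame
#'   with those columns passed as the first argument.
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, the plotted coordinates.
#' @export
plot_somatochart <- function(endomorphy, mesomorphy, ectomorphy, ...) {
  if (is.data.frame(endomorphy)) {
    df <- endomorphy
    endomorphy <- df$endomorphy; mesomorphy <- df$mesomorphy
    ectomorphy <- df$ectomorphy
  }
  pt <- somatochart_point(endomorphy, mesomorphy, ectomorphy)
  lim <- max(8, abs(pt$x), abs(pt$y))
  graphics::plot(pt$x, pt$y, xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "ectomorphy - endomorphy",
                 ylab = "2 mesomorphy - (endomorphy + ectomorphy)",
                 asp = 1, pch = 19, col = grDevices::adjustcolor("steelblue", 0.7),
                 main = "Somatochart", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::text(c(-lim * 0.9, 0, lim * 0.9), c(-lim * 0.8, lim * 0.95, -lim * 0.8),
                 c("endomorphy", "mesomorphy", "ectomorphy"), col = "grey40")
  graphics::points(0, 0, pch = 3, col = "grey40")
  invisible(pt)
}

#' Bland-Altman plot
#'
#' Differences (`predicted - reference`) against pair means, with the bias
#' line (solid) and the limits of agreement (dashed).
#'
#' @param predicted,reference numeric vectors.
#' @param z limits-of-agreement multiplier (default 1.96).
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, the [bland_altman()] statistics.
#' @export
plot_bland_altman <- function(predicted, reference, z = 1.96, ...) {
  ba <- bland_altman(predicted, reference, z)
  m <- (predicted + reference) / 2
  d <- predicted - reference
  graphics::plot(m, d, xlab = "mean of methods",
                 ylab = "difference (predicted - reference)",
                 pch = 19, col = grDevices::adjustcolor("firebrick", 0.6), ...)
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}
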