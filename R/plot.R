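#' Plot a thermal performance curve
#'
#' Base-graphics view of a [TPCCurve-class] with its characteristic points.
#'
#' @param x A [TPCCurve-class].
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "TPCCurve", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@temperature, x@value, type = "l", lwd = 2,
                   xlab = "Temperature (degC)",
                   ylab = "Net energy rate (g prey eq./y)",
                   main = sprintf("%s (%s, w = %.3g g)", x@species, x@stage,
                                  x@mass), ...)
    graphics::abline(h = 0, col = "grey60")
    graphics::abline(v = c(x@t_lo, x@t_hi), lty = 3, col = "grey40")
    graphics::abline(v = x@t_opt, lty = 2, col = "firebrick")
    invisible(x)
  })

#' Stacked bar chart of the deviation decomposition by life stage
#'
#' Mirrors the headline figure of the analysis: per life stage, the mean
#' (across species) total deviation split into its oxygen and food
#' components.
#'
#' @param dev Deviation table from [deviationStats()].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the stage-mean matrix (percent).
#' @export
plotDeviationBars <- function(dev, ...) {
  agg <- vapply(split(dev, dev$stage), function(d)
    c(oxygen = 100 * mean(d$d_oxygen, na.rm = TRUE),
      food = 100 * mean(d$d_food, na.rm = TRUE)),
    numeric(2))
  graphics::barplot(agg, beside = FALSE,
                    legend.text = c("oxygen", "food"),
                    ylab = "Deviation from fundamental TPC (%)", ...)
  invisible(agg)
}
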