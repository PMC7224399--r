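#' Diagnostic plots
#'
#' Base-graphics diagnostics: PMF profile with uncertainty band and survival
#' curve on log axes.
#'
#' @param x a [PMFProfile-class] or [SurvivalCurve-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @name plot-methods
NULL

#' @rdname plot-methods
#' @export
setMethod("plot", signature(x = "PMFProfile", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@grid, x@pmf, type = "l", xlab = x@cv,
                   ylab = "PMF (kT)", ...)
    if (length(x@stderr) == length(x@grid)) {
      graphics::lines(x@grid, x@pmf + x@stderr, lty = 3)
      graphics::lines(x@grid, pmax(x@pmf - x@stderr, 0), lty = 3)
    }
    invisible(x)
  })

#' @rdname plot-methods
#' @export
setMethod("plot", signature(x = "SurvivalCurve", y = "missing"),
  function(x, y, ...) {
    sel <- x@time > 0 & x@S > 0
    graphics::plot(x@time[sel], x@S[sel], log = "xy", type = "s",
                   xlab = "t", ylab = sprintf("S(t), %s", x@domain), ...)
    invisible(x)
  })
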