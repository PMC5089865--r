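#' Plot phenotype proportions over time
#'
#' @param x An `"esr_timeseries"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.esr_timeseries <- function(x, ...) {
  cols <- c("phen_susceptible", "phen_resistant", "phen_deflected",
            "phen_resistant_deflected")
  graphics::matplot(x$cycle, as.matrix(x[cols]), type = "l", lty = 1,
                    col = c("grey40", "firebrick", "forestgreen", "steelblue"),
                    xlab = "feeding cycle", ylab = "phenotype proportion",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = .PHENOTYPES, lty = 1, bty = "n",
                   col = c("grey40", "firebrick", "forestgreen", "steelblue"))
  invisible(x)
}

#' Heat-map of a survival-combination grid
#'
#' Establishment grids show direct establishment in light green, ratchet
#' rescue in dark green and failure in white; minimum-COR grids shade by the
#' rescuing cost of resistance.
#'
#' @param x An `"esr_grid"`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.esr_grid <- function(x, ...) {
  fr <- sort(unique(x$resistant_survival))
  fd <- sort(unique(x$deflected_survival))
  if ("classification" %in% names(x)) {
    z <- matrix(3L - as.integer(x$classification),
                length(fr), length(fd))
    graphics::image(fr, fd, z, zlim = c(0, 2),
                    col = c("white", "darkgreen", "palegreen2"),
                    xlab = "resistant per-cycle survival",
                    ylab = "deflected per-cycle survival", ...)
  } else {
    z <- matrix(x$min_cor, length(fr), length(fd))
    graphics::image(fr, fd, z,
                    col = grDevices::hcl.colors(12, "Greens", rev = TRUE),
                    xlab = "resistant per-cycle survival",
                    ylab = "deflected per-cycle survival", ...)
  }
  invisible(x)
}
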