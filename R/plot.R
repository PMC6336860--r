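# Time-course plots of a shape series (relative area/volume, neck angle and
# center distance, section radii).

#' Plot a shape time series
#'
#' Three stacked panels: relative surface area and volume; neck angle and
#' center distance; relative section radii. Written as SVG when `file` is
#' given (falls back to PDF if the SVG device is unavailable), otherwise
#' drawn on the current device.
#'
#' @param series A `"shape_time_series"`.
#' @param file Optional output path (extension decides nothing; the device
#'   does).
#' @return The path written, or `NULL` when drawn on the current device.
#' @export
plot_series <- function(series, file = NULL) {
  stopifnot(inherits(series, "shape_time_series"))
  draw <- function() {
    op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.5, 1.5, 4.5))
    on.exit(graphics::par(op))
    graphics::plot(series$t, series$S_rel, col = "blue", pch = 16, cex = 0.7,
                   xlab = "time (s)", ylab = "relative S, V",
                   ylim = range(c(series$S_rel, series$V_rel)))
    graphics::points(series$t, series$V_rel, col = "magenta", pch = 16, cex = 0.7)
    graphics::legend("topleft", c("S_rel", "V_rel"), col = c("blue", "magenta"),
                     pch = 16, bty = "n", cex = 0.8)
    ok <- is.finite(series$theta)
    if (any(ok)) {
      graphics::plot(series$t[ok], series$theta[ok], col = "red", pch = 16,
                     cex = 0.7, xlab = "time (s)", ylab = "theta (deg)")
      graphics::par(new = TRUE)
      graphics::plot(series$t[ok], series$d[ok], col = "brown", pch = 16,
                     cex = 0.7, axes = FALSE, xlab = "", ylab = "")
      graphics::axis(4)
      graphics::mtext(sprintf("d (%s)", attr(series, "units")), side = 4,
                      line = 2.5, cex = 0.7)
    } else {
      graphics::plot.new()
      graphics::text(0.5, 0.5, "no budding frames")
    }
    graphics::plot(series$t, series$r1_rel, col = "blue", pch = 16, cex = 0.7,
                   xlab = "time (s)", ylab = "relative radii",
                   ylim = range(c(series$r1_rel, series$r2_rel), na.rm = TRUE))
    ok2 <- is.finite(series$r2_rel)
    graphics::points(series$t[ok2], series$r2_rel[ok2], col = "magenta",
                     pch = 16, cex = 0.7)
    graphics::legend("topleft", c("Sec. 1", "Sec. 2"),
                     col = c("blue", "magenta"), pch = 16, bty = "n", cex = 0.8)
  }
  if (is.null(file)) {
    draw()
    return(invisible(NULL))
  }
  opened <- tryCatch({
    grDevices::svg(file, width = 6, height = 8)
    TRUE
  }, error = function(e) FALSE)
  if (!opened) {
    file <- sub("\\.svg$", ".pdf", file)
    grDevices::pdf(file, width = 6, height = 8)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  draw()
  invisible(file)
}
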