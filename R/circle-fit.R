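# Algebraic circle fitting (Taubin normalization).

#' Least-squares circle fit
#'
#' Algebraic circle fit with Taubin's gradient-weighted normalization:
#' minimizes the mean squared algebraic distance under a unit-gradient-norm
#' constraint, solved by Newton iteration on the characteristic polynomial.
#' The fit is exact (to numerical precision) when the points lie on a circle,
#' for any arc span, and is far less biased than the naive Kasa fit on short
#' arcs -- the regime that matters when fitting the mother and bud arcs of a
#' budding vesicle separately.
#'
#' @param points Two-column matrix (or data.frame) of `(x, y)` coordinates,
#'   at least 3 non-collinear points.
#' @return A [circle2d].
#' @examples
#' th <- seq(0, pi / 3, length.out = 25)
#' fit_circle(cbind(5 + 30 * cos(th), -2 + 30 * sin(th)))
#' @export
fit_circle <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop_invalid_input("`points` must have two columns (x, y)")
  if (nrow(points) < 3L) stop_invalid_input("circle fit needs at least 3 points")
  if (!all(is.finite(points))) stop_invalid_input("`points` must be finite")
  x <- points[, 1]; y <- points[, 2]
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  z <- u * u + v * v
  Muu <- mean(u * u); Mvv <- mean(v * v); Muv <- mean(u * v)
  Muz <- mean(u * z); Mvz <- mean(v * z); Mzz <- mean(z * z)
  Mz <- Muu + Mvv
  cov_xy <- Muu * Mvv - Muv * Muv
  scale2 <- Mz # squared scale of the point cloud
  if (scale2 <= 0 || cov_xy <= 1e-12 * scale2 * scale2) {
    # rank-deficient scatter: collinear (or coincident) points
    stop_fit_failure("degenerate circle fit: points are collinear")
  }
  # characteristic polynomial of the Taubin constraint (Chernov's form);
  # its smallest root eta is found by Newton from eta = 0 (convex side).
  a3 <- 4 * Mz
  a2 <- -3 * Mz * Mz - Mzz
  a1 <- Mzz * Mz + 4 * cov_xy * Mz - Muz * Muz - Mvz * Mvz - Mz * Mz * Mz
  a0 <- Muz * Muz * Mvv + Mvz * Mvz * Muu - Mzz * cov_xy -
    2 * Muz * Mvz * Muv + Mz * Mz * cov_xy
  eta <- 0
  for (iter in 1:40) {
    p <- a0 + eta * (a1 + eta * (a2 + eta * a3))
    dp <- a1 + eta * (2 * a2 + 3 * eta * a3)
    if (dp == 0) break
    step <- p / dp
    eta_new <- eta - step
    if (!is.finite(eta_new) || abs(step) < 1e-14 * (1 + abs(eta))) {
      eta <- eta_new
      break
    }
    eta <- eta_new
  }
  det <- eta * eta - eta * Mz + cov_xy
  if (!is.finite(det) || abs(det) < 1e-14 * scale2 * scale2)
    stop_fit_failure("degenerate circle fit: singular normal equations")
  cx <- (Muz * (Mvv - eta) - Mvz * Muv) / det / 2
  cy <- (Mvz * (Muu - eta) - Muz * Muv) / det / 2
  r <- sqrt(cx * cx + cy * cy + Mz)
  circle2d(cx + mx, cy + my, r)
}

# RMS of radial residuals of `points` about circle `circ`.
circle_rms <- function(points, circ) {
  dd <- sqrt((points[, 1] - circ$cx)^2 + (points[, 2] - circ$cy)^2) - circ$r
  sqrt(mean(dd^2))
}
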