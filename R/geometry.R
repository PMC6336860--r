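# Exact geometry of two intersecting spheres.
#
# A budding vesicle cross-section is modeled as two superimposed circles
# (mother section and bud section). Under rotational symmetry about the
# center-center axis the pair describes two intersecting spheres; the
# quantities of interest are the union surface area S (the two exposed
# spherical caps), union volume V, the neck radius a (radius of the circle of
# intersection) and the neck angle theta (angle between the two tangents at
# the neck in the cross-sectional plane).

#' Construct a fitted circle
#'
#' `circle2d` is the atomic output of contour fitting: a circle in image
#' coordinates (pixel or micrometer units).
#'
#' @param cx,cy Center coordinates.
#' @param r Radius; must be positive and finite.
#' @return An object of class `"circle2d"`: a list with fields `cx`, `cy`, `r`.
#' @examples
#' circle2d(0, 0, 5)
#' @export
circle2d <- function(cx, cy, r) {
  if (!all(is.finite(c(cx, cy, r)))) stop_invalid_input("circle coordinates must be finite")
  if (r <= 0) stop_invalid_input("circle radius must be positive")
  structure(list(cx = cx, cy = cy, r = r), class = "circle2d")
}

#' @export
print.circle2d <- function(x, ...) {
  cat(sprintf("<circle2d> center (%.4g, %.4g), r = %.4g\n", x$cx, x$cy, x$r))
  invisible(x)
}

#' Construct a two-circle shape (mother + bud sections)
#'
#' Ordered pair of circles describing one budding cross-section: `sec1` is the
#' mother section, `sec2` the bud section. The center distance `d` is derived.
#'
#' @param sec1,sec2 [circle2d] objects for the mother and bud sections.
#' @return An object of class `"two_circle_shape"` with fields `sec1`, `sec2`
#'   and the Euclidean center distance `d`.
#' @examples
#' two_circle_shape(circle2d(0, 0, 30), circle2d(35, 0, 20))
#' @export
two_circle_shape <- function(sec1, sec2) {
  stopifnot(inherits(sec1, "circle2d"), inherits(sec2, "circle2d"))
  d <- sqrt((sec1$cx - sec2$cx)^2 + (sec1$cy - sec2$cy)^2)
  structure(list(sec1 = sec1, sec2 = sec2, d = d), class = "two_circle_shape")
}

#' @export
print.two_circle_shape <- function(x, ...) {
  cat(sprintf("<two_circle_shape> r1 = %.4g, r2 = %.4g, d = %.4g (%s)\n",
              x$sec1$r, x$sec2$r, x$d,
              classify_configuration(x$sec1$r, x$sec2$r, x$d)))
  invisible(x)
}

# Relative tolerance used to snap d onto the tangency boundaries.
.vb_class_tol <- 1e-9

#' Classify the configuration of two circles/spheres
#'
#' Guards the validity domain of the two-circle model. Boundary equalities are
#' decided within a relative tolerance of `1e-9` (scaled by `r1 + r2 + d`).
#' The degenerate case `d = 0`, `r1 = r2` is reported as `"contained"`
#' (a single sphere), not an error.
#'
#' @param r1,r2 Radii of the mother and bud sections (> 0).
#' @param d Center distance (>= 0).
#' @return One of `"contained"`, `"internally_tangent"`, `"intersecting"`,
#'   `"externally_tangent"`, `"disjoint"`.
#' @examples
#' classify_configuration(1, 1, 1)    # "intersecting"
#' classify_configuration(1, 0.5, 2)  # "disjoint"
#' @export
classify_configuration <- function(r1, r2, d) {
  check_finite_positive(r1, "r1"); check_finite_positive(r2, "r2")
  if (!is.finite(d) || d < 0) stop_invalid_input("`d` must be finite and non-negative")
  tol <- .vb_class_tol * (r1 + r2 + d)
  if (abs(d - abs(r1 - r2)) <= tol) {
    # d = 0 with r1 = r2 is coincident circles: a single sphere.
    if (d <= tol && abs(r1 - r2) <= tol) return("contained")
    return("internally_tangent")
  }
  if (abs(d - (r1 + r2)) <= tol) return("externally_tangent")
  if (d < abs(r1 - r2)) return("contained")
  if (d > r1 + r2) return("disjoint")
  "intersecting"
}

#' Signed distances from each center to the neck plane
#'
#' For two intersecting spheres the circle of intersection (the neck) lies in
#' the radical plane. `x1` is the signed distance from center 1 to that plane
#' along the center-center axis and `x2 = d - x1` the distance from center 2,
#' satisfying `x1^2 + a^2 = r1^2` and `x2^2 + a^2 = r2^2`.
#'
#' @inheritParams classify_configuration
#' @return Named numeric vector `c(x1 = , x2 = )`.
#' @examples
#' neck_plane_offsets(3, 4, 5)  # c(x1 = 1.8, x2 = 3.2)
#' @export
neck_plane_offsets <- function(r1, r2, d) {
  cls <- classify_configuration(r1, r2, d)
  if (d == 0) stop_degenerate("neck plane undefined for concentric circles (d = 0)")
  if (cls != "intersecting")
    stop_domain(sprintf("configuration is '%s', not intersecting", cls))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  c(x1 = x1, x2 = d - x1)
}

#' Neck radius of two intersecting spheres
#'
#' Radius of the circle of intersection: the radius of the wide neck that
#' connects the mother and the bud.
#'
#' @inheritParams classify_configuration
#' @return Neck radius `a > 0`.
#' @examples
#' neck_radius(3, 4, 5)  # 2.4
#' @export
neck_radius <- function(r1, r2, d) {
  x <- neck_plane_offsets(r1, r2, d)
  a2 <- r1^2 - x[["x1"]]^2
  # numerically a2 >= 0 strictly inside the intersecting class
  sqrt(max(a2, 0))
}

#' Surface area of the union of two spheres
#'
#' Sum of the two exposed spherical-cap areas: the internal lens has no
#' physical membrane, so only the exposed surface counts. For the contained
#' (and internally tangent) configurations this is the full area of the larger
#' sphere; for disjoint or externally tangent spheres, the sum of both full
#' areas.
#'
#' @inheritParams classify_configuration
#' @return Union surface area `S`.
#' @examples
#' union_surface_area(1, 1, 1)  # 6*pi
#' @export
union_surface_area <- function(r1, r2, d) {
  cls <- classify_configuration(r1, r2, d)
  switch(cls,
    contained = ,
    internally_tangent = 4 * pi * max(r1, r2)^2,
    externally_tangent = ,
    disjoint = 4 * pi * (r1^2 + r2^2),
    intersecting = {
      x <- neck_plane_offsets(r1, r2, d)
      # exposed cap of sphere i has height r_i + x_i, area 2*pi*r_i*(r_i + x_i)
      2 * pi * r1 * (r1 + x[["x1"]]) + 2 * pi * r2 * (r2 + x[["x2"]])
    }
  )
}

#' Volume of the union of two spheres
#'
#' Sum of the two full sphere volumes minus the lens of intersection.
#'
#' @inheritParams classify_configuration
#' @return Union volume `V`.
#' @examples
#' union_volume(1, 1, 1)  # 9*pi/4
#' @export
union_volume <- function(r1, r2, d) {
  cls <- classify_configuration(r1, r2, d)
  switch(cls,
    contained = ,
    internally_tangent = 4 / 3 * pi * max(r1, r2)^3,
    externally_tangent = ,
    disjoint = 4 / 3 * pi * (r1^3 + r2^3),
    intersecting = {
      lens <- pi * (r1 + r2 - d)^2 *
        (d^2 + 2 * d * (r1 + r2) - 3 * (r1^2 + r2^2) + 6 * r1 * r2) / (12 * d)
      4 / 3 * pi * (r1^3 + r2^3) - lens
    }
  )
}

#' Neck angle between the two tangents at the neck
#'
#' In the cross-sectional plane the two fitted circles meet at the neck
#' points; `theta` is the angle between the tangent lines there, chosen as the
#' supplement of the center-neck-center angle `phi`
#' (`cos phi = (r1^2 + r2^2 - d^2) / (2 r1 r2)`). With this convention
#' `theta -> 180` as the bud merges back into the mother (internal tangency)
#' and `theta -> 0` as the neck pinches off (external tangency); for fixed
#' radii `theta` is strictly decreasing in `d`.
#'
#' @inheritParams classify_configuration
#' @return Neck angle in degrees, in (0, 180).
#' @examples
#' neck_angle(3, 4, 5)  # 90
#' neck_angle(1, 1, 1)  # 120
#' @export
neck_angle <- function(r1, r2, d) {
  cls <- classify_configuration(r1, r2, d)
  if (cls != "intersecting")
    stop_domain(sprintf("neck angle undefined for configuration '%s'", cls))
  cphi <- (r1^2 + r2^2 - d^2) / (2 * r1 * r2)
  cphi <- min(1, max(-1, cphi))
  180 - acos(cphi) * 180 / pi
}

#' Full derived geometry of a two-circle shape
#'
#' Convenience wrapper computing all derived sphere-union quantities for one
#' cross-section.
#'
#' @param shape A [two_circle_shape], or `NULL` alongside explicit radii.
#' @param r1,r2,d Alternatively, raw radii and center distance.
#' @return A list of class `"sphere_union_geometry"` with fields `S`, `V`,
#'   `a` (neck radius, `NA` unless intersecting), `theta` (degrees, `NA`
#'   unless intersecting), `x1`, `x2` (`NA` unless intersecting), and
#'   `config_class`.
#' @examples
#' sphere_union_geometry(r1 = 1, r2 = 1, d = 1)
#' @export
sphere_union_geometry <- function(shape = NULL, r1 = NULL, r2 = NULL, d = NULL) {
  if (!is.null(shape)) {
    stopifnot(inherits(shape, "two_circle_shape"))
    r1 <- shape$sec1$r; r2 <- shape$sec2$r; d <- shape$d
  }
  cls <- classify_configuration(r1, r2, d)
  out <- list(
    S = union_surface_area(r1, r2, d),
    V = union_volume(r1, r2, d),
    a = NA_real_, theta = NA_real_, x1 = NA_real_, x2 = NA_real_,
    config_class = cls
  )
  if (cls == "intersecting") {
    x <- neck_plane_offsets(r1, r2, d)
    out$x1 <- x[["x1"]]; out$x2 <- x[["x2"]]
    out$a <- neck_radius(r1, r2, d)
    out$theta <- neck_angle(r1, r2, d)
  }
  structure(out, class = "sphere_union_geometry")
}

#' Monte-Carlo estimate of the union volume
#'
#' Independent oracle for [union_volume()]: rejection sampling in the bounding
#' box of the two spheres. Used in the test suite to validate the closed form;
#' not part of the analysis pipeline.
#'
#' @inheritParams classify_configuration
#' @param n_points Number of sample points (>= 1e4).
#' @param seed Integer RNG seed (local to this call).
#' @return List with `estimate`, `stderr` (binomial standard error) and
#'   `n_points`.
#' @export
monte_carlo_union_volume <- function(r1, r2, d, n_points = 1e6, seed = 1L) {
  check_finite_positive(r1, "r1"); check_finite_positive(r2, "r2")
  if (!is.finite(d) || d < 0) stop_invalid_input("`d` must be finite and non-negative")
  if (n_points < 1e4) stop_invalid_input("`n_points` must be at least 1e4")
  # spheres centered at (0,0,0) and (d,0,0)
  lo <- c(min(-r1, d - r2), -max(r1, r2), -max(r1, r2))
  hi <- c(max(r1, d + r2), max(r1, r2), max(r1, r2))
  vol_box <- prod(hi - lo)
  n <- as.integer(n_points)
  inside <- withr_seed(seed, {
    px <- stats::runif(n, lo[1], hi[1])
    py <- stats::runif(n, lo[2], hi[2])
    pz <- stats::runif(n, lo[3], hi[3])
    (px^2 + py^2 + pz^2 <= r1^2) | ((px - d)^2 + py^2 + pz^2 <= r2^2)
  })
  phat <- mean(inside)
  list(
    estimate = phat * vol_box,
    stderr = vol_box * sqrt(phat * (1 - phat) / n),
    n_points = n
  )
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
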