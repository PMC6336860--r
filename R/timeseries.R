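# Assembling per-frame fits into normalized time series and the statistical
# analyses run on them: relative surface area and volume (normalized to the
# first kept frame), relative section radii (both normalized to the initial
# mother radius), neck angle and center distance, a first-vs-final
# Mann-Whitney comparison, and the Spearman theta-d correlation.

#' Build a normalized shape time series from per-frame fits
#'
#' Applies the sphere-union geometry to every kept frame and normalizes:
#' `S_rel` and `V_rel` by their first kept-frame values, `r1_rel` and
#' `r2_rel` both by the first kept-frame mother radius. Frames whose
#' configuration has no neck (pre-budding single circles, or contained
#' configurations) contribute to `S_rel`/`V_rel` as single spheres but are
#' masked (`NA`) in the `theta` and `d` columns. Section labels are carried
#' across frames by nearest-center continuity when fit centers are available.
#'
#' @param fits List with one element per frame: a `"fit_result"`, a
#'   [two_circle_shape], or a bare list with fields `r1`, `r2`, `d` (`r2`/`d`
#'   `NA` for single-sphere frames).
#' @param times Numeric vector of frame times. Seconds when calibrated;
#'   frame units otherwise.
#' @param um_per_px Optional spatial calibration applied to lengths (`NA` =
#'   keep pixel units).
#' @param keep Optional logical vector (QC mask); frames with `FALSE` are
#'   dropped.
#' @return Data frame of class `"shape_time_series"` with columns `frame`,
#'   `t`, `S_rel`, `V_rel`, `r1_rel`, `r2_rel`, `theta` (degrees), `d`,
#'   plus absolute `S`, `V`, `r1`, `r2`. Attribute `units` records the
#'   length unit.
#' @export
build_series <- function(fits, times, um_per_px = NA_real_, keep = NULL) {
  n <- length(fits)
  if (length(times) != n)
    stop_invalid_input("`fits` and `times` must have the same length")
  if (is.null(keep)) keep <- rep(TRUE, n)
  if (length(keep) != n) stop_invalid_input("`keep` must match `fits` in length")

  rec <- lapply(fits, normalize_fit_record)
  rec <- track_sections(rec)
  kept <- which(keep & vapply(rec, function(r) is.finite(r$r1), logical(1)))
  if (length(kept) == 0L) stop_empty_series("no frames passed QC")
  if (length(kept) < 2L)
    stop_insufficient_data("fewer than 2 kept frames; cannot build a series")

  sc <- if (is.finite(um_per_px)) um_per_px else 1
  rows <- lapply(kept, function(i) {
    r <- rec[[i]]
    r1 <- r$r1 * sc
    r2 <- if (is.finite(r$r2)) r$r2 * sc else NA_real_
    d <- if (is.finite(r$d)) r$d * sc else NA_real_
    if (is.na(r2) || is.na(d)) {
      list(S = 4 * pi * r1^2, V = 4 / 3 * pi * r1^3,
           theta = NA_real_, d = NA_real_, r1 = r1, r2 = r2)
    } else {
      cls <- classify_configuration(r1, r2, d)
      g <- sphere_union_geometry(r1 = r1, r2 = r2, d = d)
      list(S = g$S, V = g$V,
           theta = if (cls == "intersecting") g$theta else NA_real_,
           d = if (cls == "intersecting") d else NA_real_,
           r1 = r1, r2 = r2)
    }
  })
  S <- vapply(rows, `[[`, numeric(1), "S")
  V <- vapply(rows, `[[`, numeric(1), "V")
  r1v <- vapply(rows, `[[`, numeric(1), "r1")
  r2v <- vapply(rows, `[[`, numeric(1), "r2")
  out <- data.frame(
    frame = kept - 1L,
    t = times[kept],
    S_rel = S / S[1],
    V_rel = V / V[1],
    r1_rel = r1v / r1v[1],
    r2_rel = r2v / r1v[1],
    theta = vapply(rows, `[[`, numeric(1), "theta"),
    d = vapply(rows, `[[`, numeric(1), "d"),
    S = S, V = V, r1 = r1v, r2 = r2v
  )
  attr(out, "units") <- if (is.finite(um_per_px)) "um" else "px"
  class(out) <- c("shape_time_series", "data.frame")
  out
}

# Coerce one frame's fit into a plain record (r1, r2, d + optional centers).
normalize_fit_record <- function(f) {
  if (inherits(f, "fit_result")) {
    if (isTRUE(f$pre_budding) || is.null(f$shape$sec2)) {
      return(list(r1 = f$shape$sec1$r, r2 = NA_real_, d = NA_real_,
                  c1 = c(f$shape$sec1$cx, f$shape$sec1$cy), c2 = NULL))
    }
    return(list(r1 = f$shape$sec1$r, r2 = f$shape$sec2$r, d = f$shape$d,
                c1 = c(f$shape$sec1$cx, f$shape$sec1$cy),
                c2 = c(f$shape$sec2$cx, f$shape$sec2$cy)))
  }
  if (inherits(f, "two_circle_shape")) {
    return(list(r1 = f$sec1$r, r2 = f$sec2$r, d = f$d,
                c1 = c(f$sec1$cx, f$sec1$cy), c2 = c(f$sec2$cx, f$sec2$cy)))
  }
  if (is.list(f) && !is.null(f$r1)) {
    return(list(r1 = f$r1,
                r2 = if (is.null(f$r2)) NA_real_ else f$r2,
                d = if (is.null(f$d)) NA_real_ else f$d,
                c1 = NULL, c2 = NULL))
  }
  stop_invalid_input("unrecognized per-frame fit record")
}

# Nearest-center label continuity: at the first budding frame sec1 is the
# larger circle (decompose already guarantees that); afterwards sec1 follows
# the circle whose center is nearest to the previous sec1 center.
track_sections <- function(rec) {
  prev_c1 <- NULL
  for (i in seq_along(rec)) {
    r <- rec[[i]]
    if (is.null(r$c1) || is.null(r$c2) || !is.finite(r$r2)) {
      if (!is.null(r$c1)) prev_c1 <- r$c1
      next
    }
    if (!is.null(prev_c1)) {
      d11 <- sum((r$c1 - prev_c1)^2)
      d21 <- sum((r$c2 - prev_c1)^2)
      if (d21 < d11) {
        rec[[i]] <- list(r1 = r$r2, r2 = r$r1, d = r$d, c1 = r$c2, c2 = r$c1)
        r <- rec[[i]]
      }
    }
    prev_c1 <- r$c1
  }
  rec
}

#' Compare the first and final windows of a normalized series
#'
#' Takes the first and last `window_frac` of kept frames (at least 3 points
#' each) of `S_rel` or `V_rel` and compares them with [mann_whitney_u()]. A
#' growing membrane surface makes the `S_rel` windows distinguishable while
#' conserved internal volume leaves the `V_rel` windows indistinguishable.
#'
#' @param series A `"shape_time_series"`.
#' @param metric `"S_rel"` or `"V_rel"`.
#' @param window_frac Fraction of kept frames in each window (default 0.15).
#' @param alpha Significance level.
#' @param mode Passed to [mann_whitney_u()].
#' @return A `"utest_result"` (see [mann_whitney_u()]).
#' @export
compare_first_final <- function(series, metric = c("S_rel", "V_rel"),
                                window_frac = 0.15, alpha = 0.05,
                                mode = "auto") {
  metric <- match.arg(metric)
  stopifnot(inherits(series, "shape_time_series"))
  v <- series[[metric]]
  n <- length(v)
  k <- floor(window_frac * n)
  if (k < 3L)
    stop_insufficient_data(sprintf(
      "series too short: window of %d frames (< 3) at window_frac = %g", k, window_frac))
  mann_whitney_u(v[seq_len(k)], v[seq.int(n - k + 1L, n)],
                 mode = mode, alpha = alpha)
}

#' Spearman correlation between neck angle and center distance
#'
#' Rank correlation between the `theta` and `d` series over frames with a
#' valid neck. Neck closure during budding shows up as a clear negative
#' correlation: the tangent angle falls as the centers separate.
#'
#' @param series A `"shape_time_series"`.
#' @param min_frames Minimum number of valid-neck frames (default 5).
#' @return Spearman's rho in `[-1, 1]`, or `NA` (with a classed warning
#'   `"vb_undefined_correlation"`) when either series is constant.
#' @export
theta_d_correlation <- function(series, min_frames = 5L) {
  stopifnot(inherits(series, "shape_time_series"))
  ok <- is.finite(series$theta) & is.finite(series$d)
  if (sum(ok) < min_frames)
    stop_insufficient_data(sprintf(
      "only %d frames with a valid neck (>= %d required)", sum(ok), min_frames))
  th <- series$theta[ok]; dd <- series$d[ok]
  if (stats::sd(th) == 0 || stats::sd(dd) == 0) {
    warning(structure(
      class = c("vb_undefined_correlation", "warning", "condition"),
      list(message = "constant series: correlation undefined", call = sys.call())))
    return(NA_real_)
  }
  stats::cor(th, dd, method = "spearman")
}
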