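# Splitting a budding contour at the neck and fitting the two sections.

#' Decompose a contour into two superimposed circles
#'
#' Splits the contour at the two neck points, discards a guard band of
#' `guard` points around each neck point (the neck region belongs to neither
#' sphere), and fits one circle per arc. The repeated-fit averaging of the
#' original manual procedure is emulated by bootstrap resampling of the arc
#' points across `n_repeats` fits whose circle parameters are averaged.
#'
#' Section labels: `sec1` is the larger-radius circle (the mother); frame-to-
#' frame label continuity is enforced later by [build_series()] via
#' nearest-center tracking.
#'
#' @param contour A `"vb_contour"` from [extract_contour()].
#' @param n_repeats Number of bootstrap fit repeats to average (default 5).
#' @param guard Points excluded on each side of each neck point.
#' @param neck_args Optional list of arguments passed to
#'   [detect_neck_points()].
#' @return A list of class `"fit_result"`: `shape` (a [two_circle_shape], or
#'   a single [circle2d] in `$sec1` with `sec2 = NULL` for pre-budding
#'   frames), `pre_budding` flag, `rms_residual` (px), `n_repeats`,
#'   `per_repeat_shapes`.
#' @examples
#' rc <- render_config(noise_sd = 0)
#' shp <- two_circle_shape(circle2d(50, 64, 30), circle2d(85, 64, 20))
#' fit <- decompose_two_circles(extract_contour(render_frame(shp, rc)))
#' c(fit$shape$sec1$r, fit$shape$sec2$r, fit$shape$d)
#' @export
decompose_two_circles <- function(contour, n_repeats = 5L, guard = 5L,
                                  neck_args = list()) {
  stopifnot(inherits(contour, "vb_contour"))
  if (n_repeats < 1L) stop_invalid_input("`n_repeats` must be >= 1")
  pts <- contour$points
  n <- nrow(pts)
  nk <- do.call(detect_neck_points, c(list(contour), neck_args))
  if (is.null(nk)) {
    # pre-budding: a single sphere
    circ <- fit_circle(pts)
    return(structure(list(
      shape = list(sec1 = circ, sec2 = NULL, d = NA_real_),
      pre_budding = TRUE,
      rms_residual = circle_rms(pts, circ),
      n_repeats = 1L,
      per_repeat_shapes = list()
    ), class = "fit_result"))
  }
  a <- nk[1]; b <- nk[2]
  idx_arc1 <- ((a + guard):(b - guard - 1L))
  idx_arc2 <- ((b + guard):(a - guard - 1L + n))
  idx_arc1 <- ((idx_arc1 - 1L) %% n) + 1L
  idx_arc2 <- ((idx_arc2 - 1L) %% n) + 1L
  if (length(idx_arc1) < 10L || length(idx_arc2) < 10L)
    stop_fit_failure(sprintf(
      "arc too short after neck split: %d and %d points",
      length(idx_arc1), length(idx_arc2)))
  arc1 <- pts[idx_arc1, , drop = FALSE]
  arc2 <- pts[idx_arc2, , drop = FALSE]

  # robust pre-trim: near the neck the mother and bud rings overlap and the
  # ridge refinement can land on the wrong membrane; drop gross radial
  # outliers of an initial fit before bootstrapping
  arc1 <- trim_arc_outliers(arc1)
  arc2 <- trim_arc_outliers(arc2)
  if (nrow(arc1) < 10L || nrow(arc2) < 10L)
    stop_fit_failure("arc too short after outlier trimming")

  reps <- vector("list", n_repeats)
  for (k in seq_len(n_repeats)) {
    s1 <- arc1[sample.int(nrow(arc1), replace = TRUE), , drop = FALSE]
    s2 <- arc2[sample.int(nrow(arc2), replace = TRUE), , drop = FALSE]
    c1 <- fit_circle(s1)
    c2 <- fit_circle(s2)
    reps[[k]] <- list(c1 = c1, c2 = c2)
  }
  avg <- function(get) mean(vapply(reps, get, numeric(1)))
  c1 <- circle2d(avg(function(r) r$c1$cx), avg(function(r) r$c1$cy),
                 avg(function(r) r$c1$r))
  c2 <- circle2d(avg(function(r) r$c2$cx), avg(function(r) r$c2$cy),
                 avg(function(r) r$c2$r))
  # mother = larger section
  if (c2$r > c1$r) { tmp <- c1; c1 <- c2; c2 <- tmp; tmp <- arc1; arc1 <- arc2; arc2 <- tmp }
  shape <- two_circle_shape(c1, c2)
  rms <- sqrt(mean(c(
    (sqrt((arc1[, 1] - c1$cx)^2 + (arc1[, 2] - c1$cy)^2) - c1$r)^2,
    (sqrt((arc2[, 1] - c2$cx)^2 + (arc2[, 2] - c2$cy)^2) - c2$r)^2
  )))
  structure(list(shape = shape, pre_budding = FALSE, rms_residual = rms,
                 n_repeats = as.integer(n_repeats),
                 per_repeat_shapes = reps),
            class = "fit_result")
}

# Drop points whose radial residual to a first-pass circle fit is a gross
# outlier (> 3 * MAD, floored at a quarter pixel).
trim_arc_outliers <- function(arc) {
  if (nrow(arc) < 12L) return(arc)
  fit <- tryCatch(fit_circle(arc), vb_error = function(e) NULL)
  if (is.null(fit)) return(arc)
  res <- sqrt((arc[, 1] - fit$cx)^2 + (arc[, 2] - fit$cy)^2) - fit$r
  cut <- max(3 * stats::mad(res, center = stats::median(res)), 0.25)
  keep <- abs(res - stats::median(res)) <= cut
  if (sum(keep) < 10L) arc else arc[keep, , drop = FALSE]
}

#' @export
print.fit_result <- function(x, ...) {
  if (isTRUE(x$pre_budding)) {
    cat(sprintf("<fit_result> pre-budding single circle r = %.3f (rms %.3g px)\n",
                x$shape$sec1$r, x$rms_residual))
  } else {
    cat(sprintf("<fit_result> r1 = %.3f, r2 = %.3f, d = %.3f (rms %.3g px, %d repeats)\n",
                x$shape$sec1$r, x$shape$sec2$r, x$shape$d,
                x$rms_residual, x$n_repeats))
  }
  invisible(x)
}
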