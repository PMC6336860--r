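# Phase-contrast-like rendering of two-circle shapes.
#
# First-order mimicry of the phase-contrast appearance: a gray background, a
# dark membrane ring along the union-of-discs boundary (Gaussian ridge
# profile centered exactly on the true boundary, so the intensity minimum is
# an unbiased estimator of it), a bright halo just outside, a slightly darker
# interior, and the paler bud ring observed experimentally (configurable
# contrast attenuation). No optics simulation.

#' Rendering configuration
#'
#' Intensity levels are on the 8-bit scale (0-255); frames are rendered as
#' floating point and quantized on write.
#'
#' @param size Frame side length in px (square frames).
#' @param um_per_px Spatial calibration.
#' @param background Background gray level.
#' @param ring_depth Darkness of the membrane ring below background.
#' @param ring_width Full width (px) scale of the ring's Gaussian profile.
#' @param halo_height Brightness of the phase halo above background.
#' @param halo_offset Distance (px) of the halo peak outside the boundary.
#' @param halo_width Width (px) of the halo profile.
#' @param interior_offset Interior level minus background (usually negative).
#' @param bud_attenuation Fraction by which the bud ring/halo contrast is
#'   reduced relative to the mother (the buds appear paler).
#' @param noise_sd Additive Gaussian pixel noise sd (intensity levels).
#' @param blur_sigma Nominal optical blur (px) applied to sharp frames.
#' @param focus_jitter_sd Frame-to-frame sd of the blur around `blur_sigma`
#'   in [render_movie()] (clipped to 0.3-2.5 px), emulating the continuous
#'   focal drift of live time-lapse acquisition; single-frame renders use
#'   the nominal blur.
#' @param defocus_sigma Blur (px) applied to frames flagged defocused.
#' @param defocus_fraction Fraction of frames rendered defocused by
#'   [render_movie()].
#' @return A list of class `"render_config"`.
#' @export
render_config <- function(size = 128L, um_per_px = 0.2, background = 180,
                          ring_depth = 90, ring_width = 2.4,
                          halo_height = 25, halo_offset = 3, halo_width = 1.2,
                          interior_offset = -10, bud_attenuation = 0.4,
                          noise_sd = 3, blur_sigma = 0.8, focus_jitter_sd = 0.4,
                          defocus_sigma = 6, defocus_fraction = 0) {
  if (size < 32) stop_config("`size` must be at least 32 px")
  if (um_per_px <= 0) stop_config("`um_per_px` must be positive")
  if (noise_sd < 0) stop_config("`noise_sd` must be >= 0")
  if (focus_jitter_sd < 0) stop_config("`focus_jitter_sd` must be >= 0")
  if (bud_attenuation < 0 || bud_attenuation >= 1)
    stop_config("`bud_attenuation` must be in [0, 1)")
  lv <- c(background, background - ring_depth, background + halo_height,
          background + interior_offset)
  if (any(lv < 0 | lv > 255)) stop_config("intensity levels must stay within 0..255")
  structure(list(size = as.integer(size), um_per_px = um_per_px,
                 background = background, ring_depth = ring_depth,
                 ring_width = ring_width, halo_height = halo_height,
                 halo_offset = halo_offset, halo_width = halo_width,
                 interior_offset = interior_offset,
                 bud_attenuation = bud_attenuation, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, focus_jitter_sd = focus_jitter_sd,
                 defocus_sigma = defocus_sigma,
                 defocus_fraction = defocus_fraction),
            class = "render_config")
}

#' Render one frame of a budding vesicle
#'
#' Draws the union-of-discs silhouette of `shape` (coordinates in px) with a
#' dark boundary ring and bright halo; the bud's ring is attenuated by the
#' configured fraction. Noise is drawn from the current RNG state, so frames
#' are deterministic given a seed.
#'
#' @param shape A [two_circle_shape] in pixel coordinates, or a [circle2d]
#'   for a pre-budding (single sphere) frame.
#' @param rc A [render_config()].
#' @param defocused Render with the defocus blur instead of the sharp blur.
#' @param blur_sigma Optional blur override (px), used by [render_movie()]
#'   for per-frame focus jitter.
#' @return Numeric `size x size` matrix (gray levels in [0, 255]).
#' @export
render_frame <- function(shape, rc = render_config(), defocused = FALSE,
                         blur_sigma = NULL) {
  if (inherits(shape, "circle2d"))
    shape <- list(sec1 = shape, sec2 = NULL)
  circles <- list(shape$sec1)
  if (!is.null(shape$sec2)) circles <- c(circles, list(shape$sec2))
  margin <- 10
  for (ci in circles) {
    if (ci$cx - ci$r < margin || ci$cx + ci$r > rc$size - 1 - margin ||
        ci$cy - ci$r < margin || ci$cy + ci$r > rc$size - 1 - margin)
      stop_render(sprintf(
        "shape does not fit in the %d px frame with a %d px margin", rc$size, margin))
  }
  xs <- matrix(rep(0:(rc$size - 1), each = rc$size), rc$size)   # col-varying x
  ys <- matrix(rep(0:(rc$size - 1), times = rc$size), rc$size)  # row-varying y
  f1 <- sqrt((xs - shape$sec1$cx)^2 + (ys - shape$sec1$cy)^2) - shape$sec1$r
  if (is.null(shape$sec2)) {
    f <- f1
    is_bud <- matrix(FALSE, rc$size, rc$size)
  } else {
    f2 <- sqrt((xs - shape$sec2$cx)^2 + (ys - shape$sec2$cy)^2) - shape$sec2$r
    f <- pmin(f1, f2)
    is_bud <- f2 < f1
  }
  contrast <- ifelse(is_bud, 1 - rc$bud_attenuation, 1)
  w <- rc$ring_width / 2
  img <- rc$background +
    rc$interior_offset / (1 + exp(f / 2.5)) -
    contrast * rc$ring_depth * exp(-(f / w)^2) +
    contrast * rc$halo_height * exp(-((f - rc$halo_offset) / rc$halo_width)^2) *
      (f > 0)
  sigma <- if (defocused) rc$defocus_sigma
           else if (!is.null(blur_sigma)) blur_sigma
           else rc$blur_sigma
  img <- gaussian_blur(img, sigma)
  if (rc$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, rc$noise_sd), nrow(img))
  pmin(pmax(img, 0), 255)
}

#' Render a complete synthetic movie with ground truth
#'
#' Simulates a trajectory, converts it to pixel coordinates (the whole
#' trajectory is centered in the frame), renders every frame, and optionally
#' writes the frame stack (multi-page TIFF), the truth table (CSV) and a
#' manifest (JSON) for full reproducibility. A seeded subset of frames is
#' rendered defocused according to `rc$defocus_fraction`.
#'
#' @param config A [sim_config()].
#' @param rc A [render_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return A list of class `"synthetic_movie"`: `frames` (list of matrices),
#'   `truth` (data.frame in px and um), `config`, `render_config`, `seed`,
#'   and `paths` when written.
#' @export
render_movie <- function(config = sim_config(), rc = render_config(),
                         out_dir = NULL) {
  traj <- simulate_trajectory(config)
  sc <- 1 / rc$um_per_px
  # bounding box of the whole trajectory in um (mother center at origin)
  xmax <- max(traj$r1, traj$d + traj$r2, na.rm = TRUE)
  xmin <- -max(traj$r1, na.rm = TRUE)
  ymax <- max(traj$r1, traj$r2, na.rm = TRUE)
  cx_off <- (rc$size - 1) / 2 - sc * (xmin + xmax) / 2
  cy_off <- (rc$size - 1) / 2
  truth <- traj
  truth$cx1_px <- sc * traj$cx1 + cx_off
  truth$cy1_px <- sc * traj$cy1 + cy_off
  truth$r1_px <- sc * traj$r1
  truth$cx2_px <- sc * traj$cx2 + cx_off
  truth$cy2_px <- sc * traj$cy2 + cy_off
  truth$r2_px <- sc * traj$r2
  truth$d_px <- sc * traj$d

  withr_seed(config$seed, {
    n <- nrow(truth)
    truth$defocused <- stats::runif(n) < rc$defocus_fraction
    # continuous focal drift: per-frame blur around the nominal value
    truth$blur_px <- pmin(2.5, pmax(0.3,
      stats::rnorm(n, rc$blur_sigma, rc$focus_jitter_sd)))
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      sec1 <- circle2d(truth$cx1_px[i], truth$cy1_px[i], truth$r1_px[i])
      shp <- if (is.na(truth$r2_px[i])) sec1 else
        two_circle_shape(sec1, circle2d(truth$cx2_px[i], truth$cy2_px[i], truth$r2_px[i]))
      frames[[i]] <- render_frame(shp, rc, defocused = truth$defocused[i],
                                  blur_sigma = truth$blur_px[i])
    }
  })
  movie <- structure(list(frames = frames, truth = truth, config = config,
                          render_config = rc, seed = config$seed),
                     class = "synthetic_movie")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop_io(sprintf("cannot create directory '%s'", out_dir))
    paths <- list(frames = file.path(out_dir, "frames.tif"),
                  truth = file.path(out_dir, "truth.csv"),
                  manifest = file.path(out_dir, "manifest.json"))
    write_tiff_gray(lapply(frames, function(f) round(f)), paths$frames, bits = 8L)
    utils::write.csv(truth, paths$truth, row.names = FALSE)
    manifest <- list(tool = "vesiclebud",
                     version = tryCatch(as.character(utils::packageVersion("vesiclebud")),
                                        error = function(e) "dev"),
                     seed = config$seed,
                     sim_config = unclass(config),
                     render_config = unclass(rc),
                     n_frames = length(frames))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    movie$paths <- paths
  }
  movie
}

#' @export
print.synthetic_movie <- function(x, ...) {
  cat(sprintf("<synthetic_movie> %d frames of %d x %d px, seed %d\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$seed))
  invisible(x)
}
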