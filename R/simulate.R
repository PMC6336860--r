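# Ground-truthed budding trajectories.
#
# The generative model imposes the three constraints the analysis is meant to
# detect: (i) union volume follows V0 * volume_factor^(t/duration) (constant
# by default), (ii) union surface area ramps smoothly from A0 to
# A0 * area_growth_factor, and (iii) the bud-to-mother radius ratio follows a
# prescribed monotone path rho(s). At each time the two-sphere configuration
# (r1, r2, d) satisfying all three is found by 1-d root finding on the
# dimensionless isoperimetric ratio A^3 / (36 pi V^2), which runs from 1 (a
# single sphere, internal tangency) to (1+rho^2)^3 / (1+rho^3)^2 (two
# separate spheres, external tangency) as the centers separate.

#' Simulation configuration for a budding trajectory
#'
#' Defaults state the observed conditions: mothers of 7-10 um diameter
#' (default radius 4 um), relative surface area rising to ~1.2 over 600 s at
#' conserved volume, and a monotone neck closure (theta falling as d rises).
#'
#' @param duration Total simulated time in seconds.
#' @param frame_interval Seconds between frames.
#' @param r1_0 Initial mother radius in um.
#' @param area_growth_factor Final relative surface area (>= 1).
#' @param volume_factor Final relative volume (1 = conserved; < 1 covers the
#'   shrinking-volume cases).
#' @param bud_onset Time (s) at which the bud first appears; before it the
#'   vesicle is a single sphere. Set past `duration` (or set
#'   `area_growth_factor = 1` with `volume_factor = 1`) for a no-growth null
#'   trajectory.
#' @param rho_max Final bud-to-mother radius ratio; must be large enough to
#'   accommodate the area ramp (see Details).
#' @param rho_0 Bud-to-mother radius ratio when the bud first appears. The
#'   analysis window starts once a bud is resolvable, so the bud enters at a
#'   finite size; a ratio ramp starting at 0 forces an early non-monotone
#'   center distance at conserved volume.
#' @param seed Integer RNG seed recorded with the trajectory (the trajectory
#'   itself is deterministic; the seed governs rendering/noise downstream).
#' @details The maximum relative area reachable at ratio `rho` and conserved
#'   volume is `((1+rho^2)^3/(1+rho^3)^2)^(1/3)` (attained at external
#'   tangency); `area_growth_factor` beyond that bound makes the constraint
#'   system infeasible and `simulate_trajectory` signals an infeasibility
#'   error naming the first failing time.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(duration = 600, frame_interval = 10, r1_0 = 4,
                       area_growth_factor = 1.2, volume_factor = 1,
                       bud_onset = 60, rho_max = 0.75, rho_0 = 0.3,
                       seed = 0L) {
  if (duration <= 0) stop_config("`duration` must be positive")
  if (frame_interval <= 0) stop_config("`frame_interval` must be positive")
  if (r1_0 <= 0) stop_config("`r1_0` must be positive")
  if (area_growth_factor < 1) stop_config("`area_growth_factor` must be >= 1")
  if (volume_factor <= 0) stop_config("`volume_factor` must be positive")
  if (rho_max <= 0 || rho_max > 1) stop_config("`rho_max` must be in (0, 1]")
  if (rho_0 <= 0 || rho_0 > rho_max) stop_config("`rho_0` must be in (0, rho_max]")
  structure(list(duration = duration, frame_interval = frame_interval,
                 r1_0 = r1_0, area_growth_factor = area_growth_factor,
                 volume_factor = volume_factor, bud_onset = bud_onset,
                 rho_max = rho_max, rho_0 = rho_0, seed = as.integer(seed)),
            class = "sim_config")
}

smoothstep <- function(s) s * s * (3 - 2 * s)

# Dimensionless area and volume of two unit-scaled spheres (r1 = 1, r2 = rho)
# at center distance dd.
.union_ratio <- function(rho, dd) {
  a <- union_surface_area(1, rho, dd)
  v <- union_volume(1, rho, dd)
  a^3 / (36 * pi * v^2)
}

#' Simulate a ground-truth budding trajectory
#'
#' @param config A [sim_config()].
#' @return A data.frame of class `"vb_trajectory"` with one row per frame:
#'   `frame` (0-based), `t` (s), `cx1, cy1, r1, cx2, cy2, r2, d` (um; the
#'   mother center is the origin, the bud moves along +x; `NA` for
#'   single-sphere frames), `S`, `V` (um^2, um^3), `theta` (degrees, `NA`
#'   without a neck). Attribute `config` carries the input.
#' @examples
#' tr <- simulate_trajectory(sim_config(duration = 200, frame_interval = 50))
#' tr$S / tr$S[1]
#' @export
simulate_trajectory <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tt <- seq(0, config$duration, by = config$frame_interval)
  A0 <- 4 * pi * config$r1_0^2
  V0 <- 4 / 3 * pi * config$r1_0^3
  n <- length(tt)
  out <- data.frame(frame = seq_len(n) - 1L, t = tt,
                    cx1 = 0, cy1 = 0, r1 = NA_real_,
                    cx2 = NA_real_, cy2 = NA_real_, r2 = NA_real_,
                    d = NA_real_, S = NA_real_, V = NA_real_,
                    theta = NA_real_)
  for (i in seq_len(n)) {
    t0 <- tt[i]
    Vt <- V0 * config$volume_factor^(t0 / config$duration)
    if (t0 <= config$bud_onset || config$area_growth_factor == 1) {
      # single sphere at (possibly drifting) volume; area consistent
      r1 <- (3 * Vt / (4 * pi))^(1 / 3)
      out$r1[i] <- r1
      out$S[i] <- 4 * pi * r1^2
      out$V[i] <- Vt
      next
    }
    s <- (t0 - config$bud_onset) / (config$duration - config$bud_onset)
    g <- smoothstep(s)
    At <- A0 * (1 + (config$area_growth_factor - 1) * g)
    rho <- config$rho_0 + (config$rho_max - config$rho_0) * g
    q_target <- At^3 / (36 * pi * Vt^2)
    q_max <- (1 + rho^2)^3 / (1 + rho^3)^2
    if (q_target >= q_max * (1 - 1e-12))
      stop_infeasible(sprintf(
        "infeasible constraints at t = %g s: required shape ratio %.6f exceeds the maximum %.6f reachable at bud/mother ratio rho = %.3f; increase rho_max or reduce the area ramp",
        t0, q_target^(1/3), q_max^(1/3), rho))
    d_lo <- (1 - rho) * (1 + 1e-9)
    d_hi <- (1 + rho) * (1 - 1e-9)
    root <- stats::uniroot(function(dd) log(.union_ratio(rho, dd) / q_target),
                           lower = d_lo, upper = d_hi, tol = 1e-13)
    dd <- root$root
    r1 <- (Vt / union_volume(1, rho, dd))^(1 / 3)
    r2 <- rho * r1
    d <- dd * r1
    out$r1[i] <- r1; out$r2[i] <- r2; out$d[i] <- d
    out$cx2[i] <- d; out$cy2[i] <- 0
    out$S[i] <- union_surface_area(r1, r2, d)
    out$V[i] <- union_volume(r1, r2, d)
    out$theta[i] <- neck_angle(r1, r2, d)
  }
  has_neck <- which(!is.na(out$theta))
  if (length(has_neck) > 2) {
    dth <- diff(out$theta[has_neck])
    ddi <- diff(out$d[has_neck])
    if (any(dth >= 0) || any(ddi <= 0))
      stop_infeasible("trajectory is not strictly monotone in theta/d; adjust the configuration")
  }
  attr(out, "config") <- config
  class(out) <- c("vb_trajectory", "data.frame")
  out
}

#' Simulate a measured (noisy) shape time series without rendering
#'
#' Desk-scale stand-in for the full imaging pipeline used by the statistical
#' calibration tests: perturbs the ground-truth `r1`, `r2`, `d` of each frame
#' with i.i.d. multiplicative Gaussian noise emulating the fit scatter of the
#' image pipeline, then assembles the normalized series with
#' [build_series()].
#'
#' @param config A [sim_config()].
#' @param noise_sd_rel Relative standard deviation of the per-frame
#'   measurement noise on each of `r1`, `r2`, `d` (default 0.01, matching the
#'   observed end-to-end fit scatter at default render noise).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `"shape_time_series"` data.frame (see [build_series()]).
#' @export
simulate_measured_series <- function(config = sim_config(), noise_sd_rel = 0.01,
                                     seed = config$seed) {
  truth <- simulate_trajectory(config)
  n <- nrow(truth)
  withr_seed(seed, {
    noisy <- lapply(seq_len(n), function(i) {
      r1 <- truth$r1[i] * (1 + stats::rnorm(1, 0, noise_sd_rel))
      if (is.na(truth$r2[i])) {
        list(r1 = r1, r2 = NA_real_, d = NA_real_)
      } else {
        list(r1 = r1,
             r2 = truth$r2[i] * (1 + stats::rnorm(1, 0, noise_sd_rel)),
             d = truth$d[i] * (1 + stats::rnorm(1, 0, noise_sd_rel)))
      }
    })
    build_series(noisy, times = truth$t)
  })
}
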