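# Shared fixtures: everything is generated in code at test time.

# standard two-disc test shape (px): mother r1 = 30 at (50, 64),
# bud r2 = 20 at (85, 64), d = 35 (intersecting)
fixture_shape <- function() {
  two_circle_shape(circle2d(50, 64, 30), circle2d(85, 64, 20))
}

fixture_frame <- function(noise_sd = 0, blur_sigma = 0.8, seed = 1,
                          shape = fixture_shape(), ...) {
  rc <- render_config(noise_sd = noise_sd, blur_sigma = blur_sigma, ...)
  set.seed(seed)
  render_frame(shape, rc)
}

# independent brute-force oracle for the exact Mann-Whitney p-value:
# direct pairwise counting (no ranks) over all labelings
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  u_obs <- u_of(x, y)
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# analytic circle-circle intersection points of the fixture shape
fixture_neck_truth <- function(shape = fixture_shape()) {
  r1 <- shape$sec1$r; r2 <- shape$sec2$r; d <- shape$d
  off <- neck_plane_offsets(r1, r2, d)
  a <- neck_radius(r1, r2, d)
  ux <- (shape$sec2$cx - shape$sec1$cx) / d
  uy <- (shape$sec2$cy - shape$sec1$cy) / d
  base <- c(shape$sec1$cx, shape$sec1$cy) + off[["x1"]] * c(ux, uy)
  rbind(base + a * c(-uy, ux), base - a * c(-uy, ux))
}
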