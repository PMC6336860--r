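# Series assembly, normalization, first-vs-final comparison, correlation.

make_flat_fits <- function(n, r1 = 4, r2 = 2, d = 4.5) {
  lapply(seq_len(n), function(i) list(r1 = r1, r2 = r2, d = d))
}

test_that("constant shape gives relative series identically 1", {
  ser <- build_series(make_flat_fits(10), times = seq(0, 90, by = 10))
  expect_equal(ser$S_rel, rep(1, 10))
  expect_equal(ser$V_rel, rep(1, 10))
  expect_equal(ser$r1_rel, rep(1, 10))
  expect_equal(ser$r2_rel, rep(0.5, 10))
  expect_equal(ser$theta, rep(neck_angle(4, 2, 4.5), 10))
})

test_that("normalization anchors the first kept frame exactly", {
  set.seed(51)
  ser <- simulate_measured_series(sim_config(seed = 3))
  expect_identical(ser$S_rel[1], 1)
  expect_identical(ser$V_rel[1], 1)
  expect_identical(ser$r1_rel[1], 1)
})

test_that("QC mask drops frames; all-dropped raises empty series", {
  fits <- make_flat_fits(6)
  keep <- c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  ser <- build_series(fits, times = 0:5, keep = keep)
  expect_equal(nrow(ser), 4)
  expect_equal(ser$frame, c(1L, 2L, 3L, 5L))
  expect_error(build_series(fits, times = 0:5, keep = rep(FALSE, 6)),
               class = "vb_empty_series")
  expect_error(build_series(fits[1], times = 0),
               class = "vb_insufficient_data")
  expect_error(build_series(fits, times = 0:5,
                            keep = c(TRUE, rep(FALSE, 5))),
               class = "vb_insufficient_data")
})

test_that("single-sphere frames enter S/V as spheres and are masked in theta/d", {
  fits <- c(list(list(r1 = 4, r2 = NA, d = NA)), make_flat_fits(5))
  ser <- build_series(fits, times = 0:5)
  expect_true(is.na(ser$theta[1]) && is.na(ser$d[1]))
  expect_equal(ser$S[1], 4 * pi * 16)
  expect_false(anyNA(ser$theta[-1]))
  # contained configuration also masked
  fits2 <- c(make_flat_fits(2), list(list(r1 = 4, r2 = 1, d = 2)))
  ser2 <- build_series(fits2, times = 0:2)
  expect_true(is.na(ser2$theta[3]))
  expect_equal(ser2$V[3], 4 / 3 * pi * 64)
})

test_that("calibration converts px to um", {
  ser_px <- build_series(make_flat_fits(3, r1 = 20, r2 = 10, d = 22), times = 0:2)
  ser_um <- build_series(make_flat_fits(3, r1 = 20, r2 = 10, d = 22), times = 0:2,
                         um_per_px = 0.2)
  expect_identical(attr(ser_px, "units"), "px")
  expect_identical(attr(ser_um, "units"), "um")
  expect_equal(ser_um$d, ser_px$d * 0.2)
  expect_equal(ser_um$S_rel, ser_px$S_rel) # relative series unit-free
})

test_that("label continuity follows nearest centers across frames", {
  # two frames; in the second the fit reports the sections swapped
  f1 <- two_circle_shape(circle2d(0, 0, 4), circle2d(5, 0, 2.5))
  f2 <- two_circle_shape(circle2d(5.2, 0, 2.4), circle2d(0, 0, 3.9))
  ser <- build_series(list(f1, f2), times = 0:1)
  # sec1 stays the circle near the origin even though it was listed second
  expect_equal(ser$r1[2], 3.9)
  expect_equal(ser$r2[2], 2.4)
})

test_that("first-vs-final comparison distinguishes growth and not noise", {
  ser <- simulate_measured_series(sim_config(seed = 7))
  us <- compare_first_final(ser, "S_rel")
  uv <- compare_first_final(ser, "V_rel")
  expect_identical(us$verdict, "distinguishable")
  expect_identical(uv$verdict, "indistinguishable")
  expect_true(us$U >= 0 && us$U <= us$n1 * us$n2)
  # flat noiseless series: U at its midpoint, indistinguishable
  flat <- build_series(make_flat_fits(40), times = seq_len(40))
  uf <- compare_first_final(flat, "S_rel")
  expect_equal(uf$U, uf$n1 * uf$n2 / 2)
  expect_identical(uf$verdict, "indistinguishable")
  expect_error(compare_first_final(ser[1:10, ], "S_rel"),
               class = "vb_insufficient_data")
})

test_that("theta-d correlation: exact -1 for monotone pairs, ~0 for shuffles", {
  fits <- lapply(seq(0, 1, length.out = 20), function(s) {
    list(r1 = 4, r2 = 2, d = 2.2 + 3.5 * s)  # d up, theta down
  })
  ser <- build_series(fits, times = seq_len(20))
  expect_equal(theta_d_correlation(ser), -1)
  # permutation oracle: shuffled pairings average to ~0
  set.seed(52)
  th <- ser$theta; dd <- ser$d
  cors <- replicate(500, cor(sample(th), dd, method = "spearman"))
  expect_lt(abs(mean(cors)), 0.05)
  # constant series: undefined correlation signal
  cser <- build_series(make_flat_fits(8), times = 1:8)
  expect_warning(rho <- theta_d_correlation(cser),
                 class = "vb_undefined_correlation")
  expect_true(is.na(rho))
})
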