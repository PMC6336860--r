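# Contour extraction, neck detection, focus QC (on rendered ground truth).

test_that("round trip: noiseless disc render -> contour within 1 px of truth", {
  fr <- fixture_frame(shape = circle2d(64, 64, 30))
  ct <- extract_contour(fr)
  expect_s3_class(ct, "vb_contour")
  expect_gte(nrow(ct$points), 20)
  err <- sqrt((ct$points[, 1] - 64)^2 + (ct$points[, 2] - 64)^2) - 30
  expect_lt(max(abs(err)), 1)
})

test_that("blank and ambiguous frames fail segmentation with diagnostics", {
  expect_error(extract_contour(matrix(128, 64, 64)),
               class = "vb_segmentation_failure")
  # two well-separated comparable discs
  rc <- render_config(size = 160, noise_sd = 0)
  f1 <- render_frame(circle2d(40, 40, 22), rc)
  f2 <- render_frame(circle2d(115, 115, 22), rc)
  both <- pmin(f1, f2)
  expect_error(extract_contour(both), class = "vb_segmentation_failure")
})

test_that("two-disc union yields a simple closed contour with 2 concavities", {
  fr <- fixture_frame()
  ct <- extract_contour(fr)
  p <- ct$points
  # within 1 px of the union boundary everywhere
  d1 <- sqrt((p[, 1] - 50)^2 + (p[, 2] - 64)^2) - 30
  d2 <- sqrt((p[, 1] - 85)^2 + (p[, 2] - 64)^2) - 20
  expect_lt(max(abs(pmin(abs(d1), abs(d2)))), 1)
  nk <- detect_neck_points(ct)
  expect_length(nk, 2)
  # detected neck points within 2 px of the analytic intersections
  truth <- fixture_neck_truth()
  for (k in nk) {
    dmin <- min(sqrt(rowSums((truth - matrix(p[k, ], 2, 2, byrow = TRUE))^2)))
    expect_lt(dmin, 2)
  }
})

test_that("no-neck signal: perfect circle and barely-emerged bud", {
  ct <- extract_contour(fixture_frame(shape = circle2d(64, 64, 30)))
  expect_null(detect_neck_points(ct))
  # bud barely emerged: d close to r1 - r2, tiny concavity smoothed away
  shp <- two_circle_shape(circle2d(60, 64, 30), circle2d(71.5, 64, 18))
  ct2 <- extract_contour(fixture_frame(shape = shp))
  expect_null(detect_neck_points(ct2))
})

test_that("contour output is equivariant under translation and 90-degree rotation", {
  rc <- render_config(noise_sd = 0)
  base <- two_circle_shape(circle2d(50, 54, 24), circle2d(78, 54, 16))
  ct <- extract_contour(render_frame(base, rc))
  fit <- decompose_two_circles(ct, n_repeats = 1)
  # translation by (+6, +9)
  shifted <- two_circle_shape(circle2d(56, 63, 24), circle2d(84, 63, 16))
  fit_t <- decompose_two_circles(extract_contour(render_frame(shifted, rc)),
                                 n_repeats = 1)
  expect_equal(fit_t$shape$sec1$r, fit$shape$sec1$r, tolerance = 5e-3)
  expect_equal(fit_t$shape$d, fit$shape$d, tolerance = 5e-3)
  expect_equal(fit_t$shape$sec1$cx - fit$shape$sec1$cx, 6, tolerance = 0.1)
  expect_equal(fit_t$shape$sec1$cy - fit$shape$sec1$cy, 9, tolerance = 0.1)
  # 90-degree rotation (bud along +y instead of +x)
  rot <- two_circle_shape(circle2d(54, 50, 24), circle2d(54, 78, 16))
  fit_r <- decompose_two_circles(extract_contour(render_frame(rot, rc)),
                                 n_repeats = 1)
  expect_equal(fit_r$shape$sec1$r, fit$shape$sec1$r, tolerance = 5e-3)
  expect_equal(fit_r$shape$sec2$r, fit$shape$sec2$r, tolerance = 5e-3)
  expect_equal(fit_r$shape$d, fit$shape$d, tolerance = 5e-3)
})

test_that("focus score separates sharp from defocused renders and is deterministic", {
  rc <- render_config(noise_sd = 3)
  set.seed(5)
  sharp <- render_frame(fixture_shape(), rc)
  blur <- render_frame(fixture_shape(), rc, defocused = TRUE)
  ct <- extract_contour(sharp)
  s_sharp <- focus_score(sharp, ct)
  # score the defocused frame on the same band
  s_blur <- focus_score(blur, ct)
  expect_true(frame_qc(s_sharp)$keep)
  expect_false(frame_qc(s_blur)$keep)
  expect_identical(focus_score(sharp, ct), s_sharp)
})
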