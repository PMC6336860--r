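# Ground-truth trajectory generator.

test_that("defaults: volume exactly conserved, area reaches the growth factor", {
  tr <- simulate_trajectory(sim_config())
  expect_equal(nrow(tr), 61)
  v_rel <- tr$V / tr$V[1]
  expect_true(all(abs(v_rel - 1) < 1e-6))
  s_rel <- tr$S / tr$S[1]
  expect_equal(s_rel[length(s_rel)], 1.2, tolerance = 1e-6)
  expect_true(all(diff(s_rel) >= -1e-12))
})

test_that("theta strictly decreases and d strictly increases over budding frames", {
  tr <- simulate_trajectory(sim_config())
  i <- which(!is.na(tr$theta))
  expect_gt(length(i), 30)
  expect_true(all(diff(tr$theta[i]) < 0))
  expect_true(all(diff(tr$d[i]) > 0))
  expect_true(all(tr$theta[i] > 0 & tr$theta[i] < 180))
})

test_that("truth shapes satisfy the geometry invariants frame by frame", {
  tr <- simulate_trajectory(sim_config())
  for (i in which(!is.na(tr$r2))) {
    expect_identical(classify_configuration(tr$r1[i], tr$r2[i], tr$d[i]),
                     "intersecting")
    expect_equal(union_surface_area(tr$r1[i], tr$r2[i], tr$d[i]), tr$S[i])
    expect_equal(union_volume(tr$r1[i], tr$r2[i], tr$d[i]), tr$V[i])
    expect_equal(neck_angle(tr$r1[i], tr$r2[i], tr$d[i]), tr$theta[i])
  }
})

test_that("volume_factor < 1 drains volume on schedule", {
  # a shrinking volume raises the required isoperimetric ratio, so the area
  # ramp must stay gentler than the default to remain feasible
  tr <- simulate_trajectory(sim_config(volume_factor = 0.9,
                                       area_growth_factor = 1.1))
  v_rel <- tr$V / tr$V[1]
  expect_equal(v_rel[length(v_rel)], 0.9, tolerance = 1e-6)
  expect_true(all(diff(v_rel) < 0))
})

test_that("no-growth null is a constant single sphere", {
  tr <- simulate_trajectory(sim_config(area_growth_factor = 1))
  expect_true(all(is.na(tr$r2)))
  expect_equal(sd(tr$r1), 0)
})

test_that("infeasible area/ratio combinations raise a named infeasibility error", {
  expect_error(simulate_trajectory(sim_config(area_growth_factor = 1.5)),
               class = "vb_infeasible_trajectory")
  expect_error(simulate_trajectory(sim_config(area_growth_factor = 1.3,
                                              rho_max = 0.5)),
               "t = ", class = "vb_infeasible_trajectory")
})

test_that("config validation rejects bad values", {
  expect_error(sim_config(duration = 0), class = "vb_config_error")
  expect_error(sim_config(frame_interval = -1), class = "vb_config_error")
  expect_error(sim_config(area_growth_factor = 0.9), class = "vb_config_error")
  expect_error(sim_config(rho_0 = 0.9, rho_max = 0.8), class = "vb_config_error")
})

test_that("measured series adds configured noise but keeps structure", {
  ser <- simulate_measured_series(sim_config(seed = 5), noise_sd_rel = 0.01)
  tr <- simulate_trajectory(sim_config(seed = 5))
  expect_equal(nrow(ser), nrow(tr))
  # final relative area within a few percent of the ground truth ratio
  expect_lt(abs(tail(ser$S_rel, 1) - 1.2), 0.06)
  # determinism given the seed
  ser2 <- simulate_measured_series(sim_config(seed = 5), noise_sd_rel = 0.01)
  expect_identical(ser, ser2)
})
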