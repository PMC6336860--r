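# Two-sphere union geometry: closed forms, classification, oracles.

test_that("configuration classification covers all classes and boundaries", {
  expect_identical(classify_configuration(1, 1, 3), "disjoint")
  expect_identical(classify_configuration(1, 0.5, 0.2), "contained")
  expect_identical(classify_configuration(1, 1, 1), "intersecting")
  expect_identical(classify_configuration(1, 1, 2), "externally_tangent")
  expect_identical(classify_configuration(1, 0.5, 0.5), "internally_tangent")
  # boundary equalities within the relative tolerance
  expect_identical(classify_configuration(1, 1, 2 * (1 + 1e-12)), "externally_tangent")
  # degenerate coincident circles: a single sphere, not an error
  expect_identical(classify_configuration(1, 1, 0), "contained")
  expect_error(classify_configuration(-1, 1, 1), class = "vb_invalid_input")
  expect_error(classify_configuration(1, 1, -0.1), class = "vb_invalid_input")
})

test_that("neck plane offsets and neck radius match the two-equation solution", {
  expect_equal(unname(neck_plane_offsets(1, 1, 1)), c(0.5, 0.5))
  # hand-solved from x1^2 + a^2 = r1^2, (d - x1)^2 + a^2 = r2^2
  expect_equal(unname(neck_plane_offsets(3, 4, 5)), c(1.8, 3.2))
  expect_equal(unname(neck_plane_offsets(2, 1, 2)), c(1.75, 0.25))
  expect_equal(neck_radius(1, 1, 1), sqrt(3) / 2)
  expect_equal(neck_radius(3, 4, 5), 2.4)
  # tangency limit: neck closes
  expect_lt(neck_radius(1, 1, 2 - 1e-7), 1e-3)
  expect_error(neck_plane_offsets(1, 1, 3), class = "vb_domain_error")
  expect_error(neck_plane_offsets(1, 1, 0), class = "vb_degenerate_configuration")
  expect_error(neck_radius(1, 0.5, 0.2), class = "vb_domain_error")
})

test_that("union surface area: caps, contained, disjoint", {
  expect_equal(union_surface_area(1, 1, 1), 6 * pi)
  expect_equal(union_surface_area(1, 1, 2), 8 * pi)
  expect_equal(union_surface_area(1, 1, 3), 8 * pi)
  expect_equal(union_surface_area(1, 0.5, 0.1), 4 * pi)
})

test_that("union volume: lens subtraction, contained, disjoint", {
  expect_equal(union_volume(1, 1, 1), 9 * pi / 4)
  expect_equal(union_volume(1, 1, 2), 8 * pi / 3)
  expect_equal(union_volume(1, 1, 2.5), 8 * pi / 3)
  expect_equal(union_volume(1, 0.5, 0.2), 4 * pi / 3)
})

test_that("neck angle convention and worked values", {
  expect_equal(neck_angle(3, 4, 5), 90)
  expect_equal(neck_angle(1, 1, 1), 120)
  expect_gt(neck_angle(1, 1, 1e-6), 179.9)    # merge limit
  expect_lt(neck_angle(1, 1, 2 - 1e-6), 0.5)  # pinch limit
  expect_error(neck_angle(1, 1, 3), class = "vb_domain_error")
})

test_that("neck angle is strictly decreasing in d and bounded in (0, 180)", {
  for (rr in list(c(1, 1), c(3, 4), c(2, 0.7))) {
    r1 <- rr[1]; r2 <- rr[2]
    ds <- seq(abs(r1 - r2) + 1e-6, r1 + r2 - 1e-6, length.out = 50)
    th <- vapply(ds, function(d) neck_angle(r1, r2, d), numeric(1))
    expect_true(all(diff(th) < 0))
    expect_true(all(th > 0 & th < 180))
  }
})

test_that("S and V are continuous across class boundaries", {
  cases <- list(c(1, 0.6), c(2, 2), c(3, 1.2))
  for (rr in cases) {
    r1 <- rr[1]; r2 <- rr[2]
    for (db in c(abs(r1 - r2), r1 + r2)) {
      if (db == 0) next
      lo <- db * (1 - 1e-11); hi <- db * (1 + 1e-11)
      expect_equal(union_volume(r1, r2, lo), union_volume(r1, r2, hi),
                   tolerance = 1e-9)
      expect_equal(union_surface_area(r1, r2, lo), union_surface_area(r1, r2, hi),
                   tolerance = 1e-9)
    }
  }
})

test_that("geometry is symmetric under swapping the two spheres", {
  set.seed(11)
  for (k in 1:25) {
    r1 <- runif(1, 0.3, 3); r2 <- runif(1, 0.3, 3)
    d <- runif(1, 0, (r1 + r2) * 1.2)
    expect_equal(union_surface_area(r1, r2, d), union_surface_area(r2, r1, d))
    expect_equal(union_volume(r1, r2, d), union_volume(r2, r1, d))
    if (classify_configuration(r1, r2, d) == "intersecting") {
      expect_equal(neck_angle(r1, r2, d), neck_angle(r2, r1, d))
      expect_equal(neck_radius(r1, r2, d), neck_radius(r2, r1, d))
      x <- neck_plane_offsets(r1, r2, d)
      xs <- neck_plane_offsets(r2, r1, d)
      expect_equal(unname(x), unname(rev(xs)))
    }
  }
})

test_that("S scales as k^2 and V as k^3 exactly", {
  set.seed(12)
  for (k in 1:20) {
    r1 <- runif(1, 0.5, 2); r2 <- runif(1, 0.5, 2)
    d <- runif(1, 0, (r1 + r2) * 1.1)
    sc <- runif(1, 0.1, 10)
    expect_equal(union_surface_area(sc * r1, sc * r2, sc * d),
                 sc^2 * union_surface_area(r1, r2, d))
    expect_equal(union_volume(sc * r1, sc * r2, sc * d),
                 sc^3 * union_volume(r1, r2, d))
  }
})

test_that("closed-form volume agrees with the Monte-Carlo oracle", {
  # routine-suite version at 2e5 points; the full 1e6-point 5x5x5 grid runs
  # in test-acceptance.R
  cases <- list(c(1, 1, 1), c(2, 1, 2), c(1, 1, 3), c(1, 0.5, 0.2),
                c(1.5, 1, 2.4))
  for (cs in cases) {
    mc <- monte_carlo_union_volume(cs[1], cs[2], cs[3], n_points = 2e5, seed = 1)
    expect_lt(abs(mc$estimate - union_volume(cs[1], cs[2], cs[3])),
              3 * mc$stderr + 1e-12)
  }
})

test_that("sphere_union_geometry bundles all derived quantities", {
  g <- sphere_union_geometry(r1 = 1, r2 = 1, d = 1)
  expect_s3_class(g, "sphere_union_geometry")
  expect_equal(g$S, 6 * pi)
  expect_equal(g$V, 9 * pi / 4)
  expect_equal(g$theta, 120)
  expect_equal(g$a, sqrt(3) / 2)
  expect_identical(g$config_class, "intersecting")
  g2 <- sphere_union_geometry(r1 = 1, r2 = 0.3, d = 0.1)
  expect_identical(g2$config_class, "contained")
  expect_true(is.na(g2$theta))
  g3 <- sphere_union_geometry(fixture_shape())
  expect_equal(g3$theta, neck_angle(30, 20, 35))
})
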