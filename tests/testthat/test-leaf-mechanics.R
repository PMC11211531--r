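# Cantilever-beam leaf deflection and the deformation index.

test_that("leaf geometry derives theta, area and inertia", {
  g <- paper_leaf()
  expect_equal(g$theta + g$angle, 90, tolerance = 1e-9)
  expect_equal(g$area, 0.035 * 0.015, tolerance = 1e-12)
  expect_equal(section_inertia(g), 0.015 * (4e-4)^3 / 12) # 8e-14 m^4
  expect_equal(section_inertia(g), 8e-14, tolerance = 1e-12)
  # cubic thickness law and a unit case
  g2 <- leaf_geometry(0.035, 0.015, 8e-4, 33.222)
  expect_equal(section_inertia(g2) / section_inertia(g), 8)
  expect_equal(section_inertia(leaf_geometry(1, 12, 1, 45)), 1)
  expect_error(leaf_geometry(0.035, 0.015, 4e-4, 95),
               class = "leafspray_domain_error")
})

test_that("load intensity combines impact and gravity projections", {
  g <- paper_leaf()
  expect_equal(load_intensity(0, g, 50, 0), 0)
  # linear in F0 at fixed geometry and angles
  q1 <- load_intensity(1e-6, g, 50, 0)
  expect_equal(load_intensity(3e-6, g, 50, 0), 3 * q1)
  # frozen: independent symbolic evaluation of
  # (F0 sin(theta) cos(theta_t) + G cos(beta)) / (A cos^2 theta)
  expect_equal(load_intensity(paper_F0, g, 50, 3e-4), 1.610577861687586,
               tolerance = 1e-9)
})

test_that("zero load leaves the inclined profile theta * x", {
  g <- paper_leaf(); m <- paper_material()
  for (mode in c("literal", "beam")) {
    p <- deflection_profile(g, m, 0, 50, 0, mode = mode)
    expect_equal(p$y, (90 - 33.222) * pi / 180 * p$x)
    expect_equal(p$y_load, rep(0, nrow(p)))
    expect_equal(attr(p, "tip_drop"), 0)
  }
})

test_that("tip deflection matches the frozen quadrature values", {
  g <- paper_leaf(); m <- paper_material()
  # frozen: independent numeric evaluation of the closed forms at the
  # reference parameter set (theta_t = 50 deg, F0 from the 0.4 MPa chain)
  lit <- deflection_profile(g, m, paper_F0, 50, 3e-4, mode = "literal")
  bm <- deflection_profile(g, m, paper_F0, 50, 3e-4, mode = "beam")
  expect_equal(attr(lit, "tip_drop"), 9.787858526074998e-4, tolerance = 1e-9)
  expect_equal(attr(bm, "tip_drop"), 2.0787328586825693e-4, tolerance = 1e-9)
  # the two interpretations differ by a stable, documented factor
  expect_equal(attr(lit, "mode_ratio"), 4.708569687149802, tolerance = 1e-9)
  expect_equal(attr(bm, "mode_ratio"), attr(lit, "mode_ratio"))
})

test_that("deflection scales with elasticity and load as beam theory requires", {
  g <- paper_leaf(); m <- paper_material()
  soft <- leaf_material(E = m$E / 2)
  thick <- leaf_geometry(0.035, 0.015, 8e-4, 33.222)
  for (mode in c("literal", "beam")) {
    base <- attr(deflection_profile(g, m, paper_F0, 50, 3e-4, mode = mode),
                 "tip_drop")
    # halving E doubles the load-induced deflection exactly
    expect_equal(
      attr(deflection_profile(g, soft, paper_F0, 50, 3e-4, mode = mode),
           "tip_drop"), 2 * base)
    # stiffer with thickness, softer with load
    expect_lt(attr(deflection_profile(thick, m, paper_F0, 50, 3e-4,
                                      mode = mode), "tip_drop"), base)
    expect_gt(attr(deflection_profile(g, m, 2 * paper_F0, 50, 3e-4,
                                      mode = mode), "tip_drop"), base)
  }
})

test_that("parallel-to-ground threshold is l sin(beta)", {
  g <- paper_leaf()
  expect_equal(parallel_ground_threshold(g), 0.035 * sin(33.222 * pi / 180))
  expect_equal(parallel_ground_threshold(g),
               0.0191759567142863, tolerance = 1e-10) # ~19.18 mm
  # scales linearly with length
  expect_equal(parallel_ground_threshold(leaf_geometry(0.07, 0.015, 4e-4, 33.222)),
               2 * parallel_ground_threshold(g))
})

test_that("deformation index is the relative extent increase", {
  expect_equal(deformation_index(0.03, 0.03), 0)
  expect_equal(deformation_index(0.03, 0.033), 0.1)
  # the reported bottom-leaf maximum: 12.50 mm gained over 29.28 mm
  expect_equal(deformation_index(29.28e-3, (29.28 + 12.50) * 1e-3),
               0.42691256830601093, tolerance = 1e-12)
  expect_error(deformation_index(0, 0.03), class = "leafspray_domain_error")
})

test_that("rigid rotation caps the index at 1/cos(beta) - 1", {
  g <- leaf_geometry(0.035, 0.015, 4e-4, 33.22)
  expect_equal(rigid_deformation_index(g, 0), 0)
  ceiling_xi <- 1 / cos(33.22 * pi / 180) - 1 # ~0.1954
  expect_equal(rigid_deformation_index(g, parallel_ground_threshold(g)),
               ceiling_xi, tolerance = 1e-12)
  expect_equal(ceiling_xi, 0.1953527646184714, tolerance = 1e-12)
  # monotone nondecreasing up to the ceiling
  drops <- seq(0, parallel_ground_threshold(g), length.out = 20)
  expect_true(all(diff(rigid_deformation_index(g, drops)) >= 0))
})
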