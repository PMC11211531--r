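# Nozzle geometry, hydraulics, and the operating-pressure solver.

test_that("cone angle is arctan(d/h1) with ceiling-to-5 rounding", {
  expect_equal(cone_angle(0.2, 0.3), 33.690067525979785, tolerance = 1e-12)
  expect_equal(round_cone_angle(cone_angle(0.2, 0.3)), 35)
  expect_equal(cone_angle(0.3, 0.3), 45)
  expect_equal(cone_angle(1e-9, 0.3), 0, tolerance = 1e-6)
  expect_error(cone_angle(-0.1, 0.3), class = "leafspray_domain_error")
})

test_that("reach range spans nadir to cone-edge slant", {
  r <- reach_range(0.3, 35)
  expect_equal(r[["min"]], 0.3)
  expect_equal(r[["max"]], 0.36623237662843683, tolerance = 1e-12)
  expect_equal(reach_range(0.3, 0), c(min = 0.3, max = 0.3))
  expect_equal(reach_range(1, 60), c(min = 1, max = 2))
  expect_error(reach_range(0.3, 90), class = "leafspray_domain_error")
})

test_that("incidence range is (beta, beta + cone angle)", {
  expect_equal(incidence_range(33.22, 35), c(min = 33.22, max = 68.22))
  expect_equal(incidence_range(33.22, 0), c(min = 33.22, max = 33.22))
  expect_equal(incidence_range(10, 20), c(min = 10, max = 30))
})

test_that("Bernoulli exit velocity and orifice flow are consistent", {
  expect_equal(pressure_to_velocity(0), 0)
  expect_equal(pressure_to_velocity(0.4e6), sqrt(800))
  expect_equal(pressure_to_velocity(1.6e6), 2 * pressure_to_velocity(0.4e6))
  noz <- nozzle_spec()
  expect_equal(flow_rate(noz, 0), 0)
  # frozen direct evaluations of rho Cd A1 sqrt(2 dP / rho)
  expect_equal(flow_rate(noz, 0.4e6), 0.013328648814475097, tolerance = 1e-12)
  expect_equal(flow_rate(noz, 0.383e6), 0.013042339968455623, tolerance = 1e-12)
  # mass flow / (rho A1 Cd) recovers the Bernoulli velocity
  expect_equal(flow_rate(noz, 0.4e6) / (1000 * noz$A1 * noz$discharge_coef),
               pressure_to_velocity(0.4e6))
})

test_that("design envelope bundles the geometric chain", {
  env <- design_envelope(nozzle_spec(), beta = 33.22)
  expect_equal(env$gamma_rounded, 35)
  expect_equal(env$lw_min, 0.3)
  expect_equal(round(env$lw_max * 1e3), 366)
  expect_equal(env$theta_t_max, 68.22)
})

test_that("pressure solver is deterministic and brackets a dense grid scan", {
  g <- paper_leaf(); m <- paper_material(); noz <- nozzle_spec()
  w1 <- solve_operating_pressure(g, m, noz)
  w2 <- solve_operating_pressure(g, m, noz)
  expect_identical(w1$P_range, w2$P_range)
  expect_true(all(is.finite(w1$P_range)))
  expect_lt(w1$P_range[1], w1$P_range[2])

  # independent check: dense log-grid scan of the same physical chain;
  # each solved endpoint must fall inside the sign-change bracket
  tip_chain <- function(P, lw, theta_t) {
    v0 <- pressure_to_velocity(P)
    launch <- launch_state(v0, tilt = 17.5)
    v1 <- impact_velocity(launch, time_to_distance(launch, lw))
    ds <- droplet_spec(1e-3, volume_mode = "aggregate",
                       flow_rate = flow_rate(noz, P), window = 5)
    attr(deflection_profile(g, m, impact_force(ds, v1), theta_t, 3e-4),
         "tip_drop")
  }
  target <- parallel_ground_threshold(g)
  grid <- exp(seq(log(1e5), log(1e7), length.out = 400))
  for (i in 1:2) {
    ep <- w1$endpoints[i, ]
    vals <- vapply(grid, tip_chain, 1, lw = ep$lw, theta_t = ep$theta_t)
    j <- which(diff(sign(vals - target)) != 0)[1]
    expect_true(grid[j] <= ep$P && ep$P <= grid[j + 1])
  }
})

test_that("solved pressure moves with stiffness as elasticity theory requires", {
  g <- paper_leaf(); m <- paper_material(); noz <- nozzle_spec()
  base <- solve_operating_pressure(g, m, noz)$P_range
  softer <- solve_operating_pressure(g, leaf_material(E = m$E / 2), noz)$P_range
  thicker <- solve_operating_pressure(
    leaf_geometry(0.035, 0.015, 4.5e-4, 33.222), m, noz)$P_range
  bigger_drop <- solve_operating_pressure(g, m, noz, droplet_radius = 2e-3)$P_range
  expect_true(all(softer < base))       # softer leaf bends at lower pressure
  expect_true(all(thicker > base))      # thicker blade needs more pressure
  expect_true(all(bigger_drop < base))  # larger droplets carry more momentum
})

test_that("unreachable criteria raise a no-solution error", {
  g <- paper_leaf(); noz <- nozzle_spec()
  # rigid leaf never reaches parallel
  expect_error(solve_operating_pressure(g, leaf_material(E = 1e15), noz),
               class = "leafspray_no_solution")
  # a single 1 mm droplet cannot carry the required momentum below 10 MPa
  expect_error(solve_operating_pressure(g, paper_material(), noz,
                                        volume_mode = "single_droplet"),
               class = "leafspray_no_solution")
})

test_that("tidy and glance expose the solved window", {
  w <- solve_operating_pressure(paper_leaf(), paper_material(), nozzle_spec())
  td <- tidy(w)
  expect_equal(nrow(td), 2)
  expect_named(glance(w), c("P_min", "P_max", "Q_min", "Q_max",
                            "target_tip_drop", "mode", "volume_mode",
                            "window"))
  expect_equal(glance(w)$P_min, w$P_range[1])
})
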