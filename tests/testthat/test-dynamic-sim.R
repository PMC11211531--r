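# Lumped leaf dynamics, particle transport, films, stage classification.

test_that("Stokes relaxation time matches the closed form", {
  expect_equal(stokes_relaxation_time(1000, 2e-3), 12.418812016442509,
               tolerance = 1e-12)
  expect_equal(stokes_relaxation_time(1000, 4e-3),
               4 * stokes_relaxation_time(1000, 2e-3))
})

test_that("particle at equilibrium keeps its velocity", {
  p <- tibble::tibble(x = 0, y = 0, z = 1, vx = 1, vy = -2, vz = 0.5,
                      tr = 0.1, density = 1.225)
  # vc = vp and matched densities: no drag, no buoyant weight
  p2 <- particle_step(p, vc = c(1, -2, 0.5), dt = 0.01)
  expect_equal(c(p2$vx, p2$vy, p2$vz), c(1, -2, 0.5))
  expect_equal(p2$x, 0.01)
})

test_that("velocity decays exponentially toward still fluid", {
  p <- tibble::tibble(x = 0, y = 0, z = 1, vx = 3, vy = 0, vz = 0,
                      tr = 0.05, density = 1.225)
  dt <- 0.02
  p2 <- particle_step(p, vc = c(0, 0, 0), dt = dt, g = 0)
  expect_equal(p2$vx, 3 * exp(-dt / 0.05), tolerance = 1e-12)
})

test_that("modal construction matches the exact cantilever frequency within 2%", {
  for (geom in list(paper_leaf(), leaf_geometry(0.02, 0.008, 4e-4, 33.222))) {
    ml <- modal_leaf(geom, leaf_material(E = 222.85e6))
    mu <- 700 * geom$width * geom$thickness # mass per length
    omega_exact <- 1.8751^2 *
      sqrt(222.85e6 * section_inertia(geom) / (mu * geom$length^4))
    expect_equal(sqrt(ml$K / ml$M), omega_exact, tolerance = 0.02)
  }
})

test_that("leaf at rest with no load stays at rest", {
  ml <- modal_leaf(paper_leaf(), paper_material())
  for (k in 1:10) ml <- leaf_step(ml, 0, 0.001)
  expect_identical(c(ml$s, ml$sdot), c(0, 0))
})

test_that("constant load converges to the static deflection F/K", {
  ml <- modal_leaf(paper_leaf(), paper_material(), damping_ratio = 0.3)
  F <- 0.01
  for (k in 1:5000) ml <- leaf_step(ml, F, 0.001)
  expect_equal(ml$s, F / ml$K, tolerance = 1e-6)
})

test_that("free vibration reproduces the damped-oscillator closed form", {
  # gentle test oscillator: the closed form is exact, the integrator must
  # track amplitude within 0.5% over 0.5 s at dt = 1 ms
  M <- 1e-4; K <- 0.4 # omega = 63.2 rad/s
  zeta <- 0.05
  ml <- modal_leaf(paper_leaf(), paper_material())
  ml$M <- M; ml$K <- K; ml$C <- 2 * zeta * sqrt(K * M)
  s0 <- 0.01
  ml$s <- s0; ml$sdot <- 0
  ml$sddot <- -(ml$C * ml$sdot + ml$K * ml$s) / ml$M
  omega <- sqrt(K / M); omega_d <- omega * sqrt(1 - zeta^2)
  dt <- 0.001
  ts <- seq(dt, 0.5, by = dt)
  num <- vapply(ts, function(t) {
    ml <<- leaf_step(ml, 0, dt)
    ml$s
  }, 1)
  exact <- s0 * exp(-zeta * omega * ts) *
    (cos(omega_d * ts) + zeta * omega / omega_d * sin(omega_d * ts))
  expect_lt(max(abs(num - exact)), 0.005 * s0)
  # period check: zero-crossing spacing vs 2 pi / omega_d
  crossings <- ts[which(diff(sign(num)) != 0)]
  period_num <- 2 * mean(diff(crossings))
  expect_equal(period_num, 2 * pi / omega_d, tolerance = 0.005)
})

test_that("damped free vibration never gains mechanical energy", {
  ml <- modal_leaf(paper_leaf(), paper_material(), damping_ratio = 0.05)
  ml$s <- 0.005
  energy <- function(l) 0.5 * l$M * l$sdot^2 + 0.5 * l$K * l$s^2
  e <- numeric(500)
  for (k in 1:500) {
    ml <- leaf_step(ml, 0, 0.001)
    e[k] <- energy(ml)
  }
  expect_true(all(diff(e) <= 1e-15))
})

test_that("impact detection finds aimed particles and ignores misses", {
  plant <- build_plant()
  none <- detect_impacts(
    tibble::tibble(x = double(), y = double(), z = double(),
                   vx = double(), vy = double(), vz = double(),
                   mass = double(), state = character()),
    plant, 0.001)
  expect_equal(nrow(none), 0)

  lv <- plant$leaves[1, ] # bottom leaf along azimuth 0
  # aim straight down at the mid-blade point
  be <- lv$beta * pi / 180
  mid <- c(lv$attach_x + 0.5 * lv$length * cos(be), lv$attach_y,
           lv$attach_z + 0.5 * lv$length * sin(be))
  p <- tibble::tibble(x = mid[1], y = mid[2], z = mid[3] + 0.005,
                      vx = 0, vy = 0, vz = -10, mass = 4.2e-6,
                      state = "airborne")
  ev <- detect_impacts(p, plant, 0.001)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$leaf, 1L)
  expect_equal(ev$s_along, 0.5 * lv$length, tolerance = 1e-9)
  expect_equal(ev$mass, 4.2e-6)
  expect_equal(ev$v_normal, 10 * cos(be), tolerance = 1e-9)

  # a particle far outside every patch yields nothing
  p_miss <- dplyr::mutate(p, x = 0.5)
  expect_equal(nrow(detect_impacts(p_miss, plant, 0.001)), 0)
})

test_that("film updates conserve deposited volume and superpose linearly", {
  film <- wall_film(paper_leaf())
  expect_equal(film_volume(film), 0)
  expect_identical(film_update(film, NULL)$h, film$h)

  v <- 4.2e-9
  ev <- tibble::tibble(s_along = 0.0175, s_across = 0, volume = v)
  f1 <- film_update(film, ev)
  expect_equal(film_volume(f1), v, tolerance = 1e-15)
  expect_true(all(f1$h >= 0))
  # a second identical deposit doubles the thickness everywhere it falls
  f2 <- film_update(f1, ev)
  expect_equal(f2$h, 2 * f1$h, tolerance = 1e-12)
  expect_equal(film_volume(f2), 2 * v, tolerance = 1e-15)
})

test_that("stage classification is monotone and threshold-driven", {
  # no droplets: targeted movement throughout
  quiet <- tibble::tibble(impacts_cum = rep(0L, 5), xi_frac = 0, drop_frac = 0)
  expect_true(all(classify_stage(quiet) == "targeted_movement"))
  # forced past-parallel deflection: strong impact and drainage
  forced <- tibble::tibble(impacts_cum = 10L, xi_frac = 1, drop_frac = 1.2)
  expect_equal(as.character(classify_stage(forced)),
               rep("strong_impact_drainage", 1))
  # a full ramp visits the stages in order
  ramp <- tibble::tibble(
    impacts_cum = c(0L, 0L, 1L, 3L, 8L, 20L),
    xi_frac = c(0, 0, 0.1, 0.6, 0.9, 1),
    drop_frac = c(0, 0, 0.05, 0.4, 0.9, 1.5))
  st <- classify_stage(ramp)
  expect_true(all(diff(as.integer(st)) >= 0))
  expect_equal(as.character(st[c(1, 3, 4, 6)]),
               c("targeted_movement", "contact_diffusion",
                 "continuous_coverage", "strong_impact_drainage"))
})
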