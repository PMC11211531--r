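# Reduced-order spray-plant interaction: one modal coordinate per leaf
# (first bending mode), discrete particle transport with exponential drag
# relaxation, film-mediated load transfer, four-stage classification.

#' Simulation configuration
#'
#' @param dt Time step (s).
#' @param duration Total simulated time (s).
#' @param domain Computational box (m), `c(Lx, Ly, Lz)`; the plant sits at
#'   the origin on the ground plane, the nozzle on the box axis.
#' @param air_density Continuous-phase density (kg/m^3).
#' @param air_viscosity Continuous-phase dynamic viscosity (kg/(m s)).
#' @param seed Integer seed controlling droplet emission directions.
#' @param restitution Normal restitution coefficient e for rebounding or
#'   splashed droplets, in `[0, 1]`.
#' @param splash_threshold Normal impact speed (m/s) above which a first
#'   impact splashes rather than rebounds.
#' @param rebound_cutoff Normal impact speed (m/s) below which a first
#'   impact deposits directly.
#' @param film_response_time Time constant (s) of film-mediated load
#'   transfer: droplet momentum reaches the leaf structure as a force pulse
#'   relaxing with this constant rather than as an instantaneous impulse,
#'   reflecting that pressure is transmitted through the wall film.
#' @param jet_speed Continuous-phase downward jet speed inside the spray
#'   cone (m/s); `NULL` uses the nozzle exit velocity.
#' @return A `sim_config` list.
#' @examples
#' sim_config(seed = 7)
#' @export
sim_config <- function(dt = 0.001, duration = 0.5,
                       domain = c(0.1, 0.1, 0.3),
                       air_density = AIR_DENSITY,
                       air_viscosity = AIR_VISCOSITY,
                       seed = 1, restitution = 0.3,
                       splash_threshold = 15, rebound_cutoff = 1,
                       film_response_time = 0.02,
                       jet_speed = NULL) {
  check_positive(dt, "dt")
  check_nonneg(duration, "duration")
  if (duration > 0 && duration < dt) stop_domain("`duration` must be >= dt")
  if (!is.finite(restitution) || restitution < 0 || restitution > 1) {
    stop_domain("`restitution` must be in [0, 1]")
  }
  structure(
    list(dt = dt, duration = duration, domain = domain,
         air_density = air_density, air_viscosity = air_viscosity,
         seed = as.integer(seed), restitution = restitution,
         splash_threshold = splash_threshold,
         rebound_cutoff = rebound_cutoff,
         film_response_time = film_response_time,
         jet_speed = jet_speed),
    class = "sim_config"
  )
}

#' Stokes relaxation time of a droplet
#'
#' \deqn{t_r = \rho_p d^2 / (18\mu)} — the time constant with which a
#' droplet's velocity approaches the surrounding fluid's.
#'
#' @param density Droplet density (kg/m^3).
#' @param diameter Droplet diameter (m).
#' @param viscosity Fluid dynamic viscosity (kg/(m s)).
#' @return Relaxation time (s).
#' @examples
#' stokes_relaxation_time(1000, 2e-3)  # ~12.4 s for a 2 mm droplet in air
#' @export
stokes_relaxation_time <- function(density, diameter,
                                   viscosity = AIR_VISCOSITY) {
  check_positive(density, "density")
  check_positive(diameter, "diameter")
  check_positive(viscosity, "viscosity")
  density * diameter^2 / (18 * viscosity)
}

#' Lumped modal representation of one leaf
#'
#' The leaf's first bending mode is condensed to a single tip-equivalent
#' coordinate: stiffness is the static tip stiffness \eqn{K = 3EI/l^3} and
#' the modal mass is the classical tip-equivalent cantilever value
#' \eqn{M = (33/140)\, m_{leaf}}; the resulting natural frequency
#' \eqn{\sqrt{K/M}} matches the exact first Euler-Bernoulli cantilever
#' frequency to within 1.5%. Damping is proportional,
#' \eqn{C = 2\zeta\sqrt{KM}}.
#'
#' @param geom A [leaf_geometry()].
#' @param mat A [leaf_material()].
#' @param position Attachment point on the stem (m), length-3.
#' @param azimuth Growth direction in the horizontal plane (degrees).
#' @param damping_ratio Modal damping ratio zeta.
#' @param id Leaf identifier.
#' @return A `modal_leaf` list with `M`, `C`, `K`, state `s`, `sdot`,
#'   `sddot` (tip-equivalent displacement, m) and the leaf frame.
#' @examples
#' modal_leaf(leaf_geometry(0.035, 0.015, 4e-4, 33.222), leaf_material())
#' @export
modal_leaf <- function(geom, mat, position = c(0, 0, 0), azimuth = 0,
                       damping_ratio = 0.05, id = 1L) {
  m_leaf <- mat$density * geom$length * geom$width * geom$thickness
  K <- 3 * mat$E * section_inertia(geom) / geom$length^3
  M <- 33 / 140 * m_leaf
  C <- 2 * damping_ratio * sqrt(K * M)
  structure(
    list(id = id, geom = geom, mat = mat, position = position,
         azimuth = azimuth, M = M, C = C, K = K,
         damping_ratio = damping_ratio,
         s = 0, sdot = 0, sddot = 0),
    class = "modal_leaf"
  )
}

#' @export
print.modal_leaf <- function(x, ...) {
  cat(sprintf(
    "<modal_leaf %s> M = %.3g kg, K = %.3g N/m, C = %.3g N s/m (f1 = %.1f Hz), s = %.3g mm\n",
    x$id, x$M, x$K, x$C, sqrt(x$K / x$M) / (2 * pi), x$s * 1e3))
  invisible(x)
}

#' One implicit time step of the leaf's modal equation of motion
#'
#' Advances \eqn{M\ddot s + C\dot s + K s = F} by one Newmark
#' average-acceleration step (unconditionally stable; energy-conserving for
#' `C = 0`, dissipative for `C > 0`).
#'
#' @param leaf A [modal_leaf()].
#' @param F_applied Applied modal force over the step (N).
#' @param dt Time step (s).
#' @return The updated `modal_leaf`.
#' @export
leaf_step <- function(leaf, F_applied, dt) {
  check_positive(dt, "dt")
  s0 <- leaf$s; v0 <- leaf$sdot; a0 <- leaf$sddot
  denom <- leaf$M + dt / 2 * leaf$C + dt^2 / 4 * leaf$K
  a1 <- (F_applied - leaf$C * (v0 + dt / 2 * a0) -
           leaf$K * (s0 + dt * v0 + dt^2 / 4 * a0)) / denom
  leaf$s <- s0 + dt * v0 + dt^2 / 4 * (a0 + a1)
  leaf$sdot <- v0 + dt / 2 * (a0 + a1)
  leaf$sddot <- a1
  leaf
}

# matrix core of the particle update: exact exponential relaxation toward
# the local equilibrium velocity when vc and the extra force are constant
# over the step; position advanced with the updated velocity.
.particle_step_mat <- function(pos, vel, vc, tr, dt, rho_p, rho_c, g,
                               accel_extra = NULL) {
  gvec <- c(0, 0, -g)
  buoy <- rep((rho_p - rho_c) / rho_p, length.out = nrow(pos))
  acc <- outer(buoy, gvec)
  if (!is.null(accel_extra)) acc <- acc + accel_extra
  if (is.null(dim(vc))) vc <- matrix(vc, nrow(pos), 3, byrow = TRUE)
  v_eq <- vc + acc * tr
  decay <- exp(-dt / tr)
  vel_new <- v_eq + (vel - v_eq) * decay
  list(pos = pos + vel_new * dt, vel = vel_new)
}

#' Advance airborne droplets by one drag-relaxation step
#'
#' Integrates the particle force balance — drag toward the continuous-phase
#' velocity with time constant `tr`, gravity reduced by buoyancy
#' \eqn{g(\rho_p - \rho_c)/\rho_p}, and any additional specific force — using
#' the exact exponential-relaxation solution over the step, then advances
#' positions with the updated velocity (semi-implicit).
#'
#' @param particles Tibble with columns `x`, `y`, `z`, `vx`, `vy`, `vz`,
#'   `tr` (relaxation time, s) and `density` (kg/m^3).
#' @param vc Continuous-phase velocity: length-3 vector or an n-by-3 matrix.
#' @param dt Time step (s).
#' @param accel_extra Optional n-by-3 matrix of additional specific force
#'   (m/s^2), i.e. F/mp.
#' @param rho_c Continuous-phase density (kg/m^3).
#' @param g Gravitational acceleration (m/s^2).
#' @return The particles tibble with updated positions and velocities.
#' @examples
#' p <- tibble::tibble(x = 0, y = 0, z = 0.3, vx = 0, vy = 0, vz = -28,
#'                     tr = 12.4, density = 1000)
#' particle_step(p, vc = c(0, 0, 0), dt = 0.001)
#' @export
particle_step <- function(particles, vc, dt, accel_extra = NULL,
                          rho_c = AIR_DENSITY, g = GRAVITY) {
  check_positive(dt, "dt")
  pos <- as.matrix(particles[, c("x", "y", "z")])
  vel <- as.matrix(particles[, c("vx", "vy", "vz")])
  upd <- .particle_step_mat(pos, vel, vc, particles$tr, dt,
                            particles$density, rho_c, g, accel_extra)
  particles$x <- unname(upd$pos[, 1]); particles$y <- unname(upd$pos[, 2])
  particles$z <- unname(upd$pos[, 3])
  particles$vx <- unname(upd$vel[, 1]); particles$vy <- unname(upd$vel[, 2])
  particles$vz <- unname(upd$vel[, 3])
  particles
}

# Orthonormal frame of each leaf patch: origin p0 at the attachment,
# u along the blade (inclined at beta above horizontal), w across the blade,
# n the upward-tilted normal.
.leaf_frames <- function(plant) {
  lv <- plant$leaves
  purrr::map(seq_len(nrow(lv)), function(i) {
    az <- deg2rad(lv$azimuth[i]); be <- deg2rad(lv$beta[i])
    u <- c(cos(be) * cos(az), cos(be) * sin(az), sin(be))
    w <- c(-sin(az), cos(az), 0)
    n <- c(u[2] * w[3] - u[3] * w[2],
           u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
    list(p0 = c(lv$attach_x[i], lv$attach_y[i], lv$attach_z[i]),
         u = u, w = w, n = n, length = lv$length[i], width = lv$width[i])
  })
}

#' Detect droplet impacts on the plant's leaf patches
#'
#' Each airborne (or rebounded/splashed) particle whose straight step
#' segment crosses a leaf's rectangular patch within the time step yields
#' one impact event carrying the crossing point in leaf-local coordinates,
#' the normal approach speed and the particle's momentum. When a segment
#' crosses several leaves, the first crossing along the segment wins.
#'
#' @param particles Tibble with `x`, `y`, `z`, `vx`, `vy`, `vz`, `mass`
#'   and `state` (only `"airborne"`, `"rebounded"`, `"splashed"` rows are
#'   tested).
#' @param plant A plant from [build_plant()].
#' @param dt Time step (s) used to extend the step segment.
#' @return A tibble of events: `particle` (row index), `leaf`, `frac`
#'   (position of the crossing along the step), `s_along`, `s_across`
#'   (leaf-local coordinates, m), `v_normal` (m/s, positive toward the
#'   leaf), `mass` (kg).
#' @export
detect_impacts <- function(particles, plant, dt) {
  check_positive(dt, "dt")
  frames <- .leaf_frames(plant)
  if (any(vapply(frames, function(f) f$length * f$width, 1) <= 0)) {
    stop_domain("degenerate zero-area leaf patch")
  }
  active <- which(particles$state %in% c("airborne", "rebounded", "splashed"))
  empty <- tibble(particle = integer(), leaf = integer(), frac = double(),
                  s_along = double(), s_across = double(),
                  v_normal = double(), mass = double())
  if (length(active) == 0) return(empty)
  p0m <- as.matrix(particles[active, c("x", "y", "z")])
  vel <- as.matrix(particles[active, c("vx", "vy", "vz")])
  det <- .detect_core(p0m, p0m + vel * dt, vel, frames)
  got <- which(!vapply(det$best, is.null, TRUE))
  if (length(got) == 0) return(empty)
  tibble(
    particle = active[got],
    leaf = vapply(det$best[got], function(b) as.integer(b$leaf), 1L),
    frac = det$frac[got],
    s_along = vapply(det$best[got], `[[`, 1, "s_along"),
    s_across = vapply(det$best[got], `[[`, 1, "s_across"),
    v_normal = vapply(det$best[got], `[[`, 1, "v_normal"),
    mass = particles$mass[active[got]]
  )
}

#' Wall film on a leaf surface
#'
#' A per-leaf thickness map over a regular grid in leaf-local coordinates.
#' Deposits add liquid following the film profile
#' \eqn{h = h_0 + (x^2 + y^2)/2R} about the deposit centre, truncated at
#' the stain spread radius and normalized so the integrated added thickness
#' equals the deposited volume exactly.
#'
#' @param geom A [leaf_geometry()].
#' @param nx,ny Grid cells along and across the blade.
#' @param curvature_radius Equivalent curvature radius R of the film
#'   profile (m).
#' @param base_thickness Central-profile shape constant h0 (m).
#' @param spread_radius Radius over which one deposit spreads (m);
#'   conventionally twice the droplet radius.
#' @return A `wall_film` with thickness matrix `h` (m), cell coordinates
#'   and `cell_area` (m^2).
#' @export
wall_film <- function(geom, nx = 10, ny = 5, curvature_radius = 1e-3,
                      base_thickness = 1e-3, spread_radius = 2e-3) {
  check_positive(curvature_radius, "curvature_radius")
  check_positive(spread_radius, "spread_radius")
  xs <- (seq_len(nx) - 0.5) / nx * geom$length
  ys <- ((seq_len(ny) - 0.5) / ny - 0.5) * geom$width
  structure(
    list(h = matrix(0, nx, ny), xs = xs, ys = ys,
         cell_area = (geom$length / nx) * (geom$width / ny),
         curvature_radius = curvature_radius,
         base_thickness = base_thickness,
         spread_radius = spread_radius, geom = geom),
    class = "wall_film"
  )
}

#' Film volume (m^3)
#' @param film A [wall_film()].
#' @export
film_volume <- function(film) sum(film$h) * film$cell_area

#' Add deposit events to a wall film
#'
#' Each event stamps the parabolic film profile about its centre; the
#' stamp is scaled so the added film volume equals the deposited volume
#' (volume conservation to machine precision). Film thickness never
#' decreases within a run. The load the film transfers to the leaf is its
#' weight, i.e. a pressure \eqn{\rho g h} proportional to the local
#' thickness.
#'
#' @param film A [wall_film()].
#' @param events Tibble with `s_along`, `s_across` (m) and `volume` (m^3).
#' @return The updated `wall_film`.
#' @export
film_update <- function(film, events) {
  if (is.null(events) || nrow(events) == 0) return(film)
  nx <- length(film$xs); ny <- length(film$ys)
  for (k in seq_len(nrow(events))) {
    dx <- outer(film$xs - events$s_along[k], rep(1, ny))
    dy <- outer(rep(1, nx), film$ys - events$s_across[k])
    r2 <- dx^2 + dy^2
    shape <- (film$base_thickness + r2 / (2 * film$curvature_radius)) *
      (r2 <= film$spread_radius^2)
    tot <- sum(shape) * film$cell_area
    if (tot <= 0) { # spread radius smaller than a cell: nearest cell
      i <- which.min(abs(film$xs - events$s_along[k]))
      j <- which.min(abs(film$ys - events$s_across[k]))
      film$h[i, j] <- film$h[i, j] + events$volume[k] / film$cell_area
    } else {
      film$h <- film$h + shape * (events$volume[k] / tot)
    }
  }
  film
}

#' Classify the interaction stage over a run history
#'
#' The four-stage classification of the spray-plant interaction:
#' *targeted movement* until the first droplet impact; *contact and
#' diffusion* until the deformation index reaches half its
#' parallel-to-ground value; *continuous coverage* until the tip descent
#' exceeds the parallel-to-ground threshold; *strong impact and drainage*
#' beyond it. Stages are monotone by construction (a stage once entered is
#' never left).
#'
#' @param history Tibble with columns `impacts_cum` (cumulative impact
#'   count), `xi_frac` (deformation index relative to its
#'   parallel-to-ground value) and `drop_frac` (tip descent relative to the
#'   parallel-to-ground threshold), one row per time step.
#' @return A factor vector of stage labels, one per row.
#' @export
classify_stage <- function(history) {
  lv <- c("targeted_movement", "contact_diffusion",
          "continuous_coverage", "strong_impact_drainage")
  touched <- cumsum(history$impacts_cum > 0) > 0
  half <- cumsum(history$xi_frac >= 0.5) > 0
  past <- cumsum(history$drop_frac > 1) > 0
  idx <- 1L + touched + (touched & half) + (touched & half & past)
  factor(lv[idx], levels = lv)
}
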