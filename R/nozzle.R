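#' Nozzle geometry and hydraulics specification
#'
#' @param outlet_radius Nozzle outlet radius R1 (m); reference value 0.5 mm.
#' @param discharge_coef Discharge (flow) coefficient Cd, in (0, 1];
#'   hydraulic cone nozzles sit around 0.6-0.7.
#' @param height Ground clearance h1 of the nozzle (m); set to the typical
#'   weed height, 300 mm.
#' @param lateral_range Lateral spray range d on each side (m); half the
#'   crop row spacing, 200 mm.
#' @param round_to Rounding granularity for the cone angle (degrees); the
#'   working cone angle is the computed angle rounded up to the next
#'   multiple of this value.
#' @return A `nozzle_spec` list with derived outlet area `A1`, cone angle
#'   `gamma` (degrees) and working value `gamma_rounded`.
#' @examples
#' nozzle_spec()
#' @export
nozzle_spec <- function(outlet_radius = 5e-4, discharge_coef = 0.6,
                        height = 0.3, lateral_range = 0.2, round_to = 5) {
  check_positive(outlet_radius, "outlet_radius")
  check_positive(height, "height")
  check_positive(lateral_range, "lateral_range")
  if (!is.finite(discharge_coef) || discharge_coef <= 0 || discharge_coef > 1) {
    stop_domain("`discharge_coef` must be in (0, 1]")
  }
  gamma <- cone_angle(lateral_range, height)
  structure(
    list(outlet_radius = outlet_radius, discharge_coef = discharge_coef,
         height = height, lateral_range = lateral_range,
         A1 = pi * outlet_radius^2, gamma = gamma,
         gamma_rounded = round_cone_angle(gamma, round_to)),
    class = "nozzle_spec"
  )
}

#' @export
print.nozzle_spec <- function(x, ...) {
  cat(sprintf(
    "<nozzle_spec> R1 = %g mm, Cd = %g, h1 = %g mm, d = %g mm, gamma = %.4f deg (-> %g deg)\n",
    x$outlet_radius * 1e3, x$discharge_coef, x$height * 1e3,
    x$lateral_range * 1e3, x$gamma, x$gamma_rounded))
  invisible(x)
}

#' Spray cone angle from lateral range and ground clearance
#'
#' \deqn{\gamma = \arctan(d / h_1)} in degrees: the half-apex angle needed
#' for the cone to cover a lateral range `d` at ground level from height
#' `h1`.
#'
#' @param d Lateral spray range (m).
#' @param h1 Nozzle ground clearance (m).
#' @return Cone angle (degrees).
#' @examples
#' cone_angle(0.2, 0.3)  # 33.69 degrees, working value 35
#' @export
cone_angle <- function(d, h1) {
  check_positive(d, "d")
  check_positive(h1, "h1")
  rad2deg(atan(d / h1))
}

#' Round a cone angle up to the working granularity
#'
#' Nozzle cores come in coarse cone-angle steps, so the computed angle is
#' rounded up to the next multiple of `to` degrees (33.69 -> 35).
#'
#' @param gamma Cone angle (degrees).
#' @param to Granularity (degrees).
#' @return Rounded angle (degrees).
#' @export
round_cone_angle <- function(gamma, to = 5) {
  check_positive(to, "to")
  ceiling(gamma / to) * to
}

#' Nozzle-to-target distance range across the spray cone
#'
#' Directly beneath the nozzle the travel distance is the ground clearance
#' `h1`; at the cone edge it is the slant distance `h1 / cos(gamma)`.
#'
#' @param h1 Ground clearance (m).
#' @param gamma_rounded Working cone angle (degrees), in `[0, 90)`.
#' @return Named numeric vector `c(min, max)` (m).
#' @examples
#' reach_range(0.3, 35)  # 300 mm to ~366 mm
#' @export
reach_range <- function(h1, gamma_rounded) {
  check_positive(h1, "h1")
  if (!is.finite(gamma_rounded) || gamma_rounded < 0 || gamma_rounded >= 90) {
    stop_domain("`gamma_rounded` must be in [0, 90) degrees")
  }
  c(min = h1, max = h1 / cos(deg2rad(gamma_rounded)))
}

#' Droplet incidence-angle interval on the leaf
#'
#' Spray arriving along the cone axis meets the leaf normal at the leaf
#' angle `beta`; at the cone edge the incidence grows by the working cone
#' angle, giving the interval `(beta, beta + gamma_rounded)`.
#'
#' @param beta Leaf angle (degrees), in (0, 90).
#' @param gamma_rounded Working cone angle (degrees).
#' @return Named numeric vector `c(min, max)` (degrees).
#' @examples
#' incidence_range(33.22, 35)  # (33.22, 68.22)
#' @export
incidence_range <- function(beta, gamma_rounded) {
  if (!is.finite(beta) || beta <= 0 || beta >= 90) {
    stop_domain("`beta` must be in (0, 90) degrees")
  }
  check_nonneg(gamma_rounded, "gamma_rounded")
  c(min = beta, max = beta + gamma_rounded)
}

#' Nozzle exit velocity from spraying pressure
#'
#' Bernoulli relation \eqn{P/\rho g = v_0^2 / 2g}, i.e.
#' \eqn{v_0 = \sqrt{2P/\rho}}.
#'
#' @param P Spraying (gauge) pressure (Pa); vectorized.
#' @param rho Liquid density (kg/m^3).
#' @return Exit speed v0 (m/s).
#' @examples
#' pressure_to_velocity(0.4e6)  # ~28.28 m/s
#' @export
pressure_to_velocity <- function(P, rho = WATER_DENSITY) {
  check_nonneg(P, "P")
  check_positive(rho, "rho")
  sqrt(2 * P / rho)
}

#' Nozzle mass flow from pressure difference
#'
#' Orifice discharge law \eqn{Q = C_d A_1 \sqrt{2\Delta P/\rho}} gives the
#' volumetric flow; it is multiplied by the liquid density to report the
#' mass flow in kg/s. The pressure difference is taken as the gauge
#' spraying pressure.
#'
#' @param spec A [nozzle_spec()].
#' @param dP Pressure difference (Pa); vectorized.
#' @param rho Liquid density (kg/m^3).
#' @return Mass flow Q (kg/s).
#' @examples
#' flow_rate(nozzle_spec(), dP = 0.4e6)  # ~0.0133 kg/s
#' @export
flow_rate <- function(spec, dP, rho = WATER_DENSITY) {
  check_nonneg(dP, "dP")
  rho * spec$discharge_coef * spec$A1 * sqrt(2 * dP / rho)
}

#' Geometric design envelope of the nozzle
#'
#' Collects the cone angle, the reach range and the incidence-angle
#' interval for a nozzle spec and a leaf angle.
#'
#' @param spec A [nozzle_spec()].
#' @param beta Leaf angle (degrees).
#' @return A one-row tibble with `gamma`, `gamma_rounded`, `lw_min`,
#'   `lw_max` (m), `theta_t_min`, `theta_t_max` (degrees).
#' @examples
#' design_envelope(nozzle_spec(), beta = 33.22)
#' @export
design_envelope <- function(spec, beta) {
  lw <- reach_range(spec$height, spec$gamma_rounded)
  tht <- incidence_range(beta, spec$gamma_rounded)
  tibble(
    gamma = spec$gamma, gamma_rounded = spec$gamma_rounded,
    lw_min = lw[["min"]], lw_max = lw[["max"]],
    theta_t_min = tht[["min"]], theta_t_max = tht[["max"]]
  )
}

#' Solve the spraying-pressure window for parallel-to-ground deflection
#'
#' For each matched endpoint of the spray cone — (shortest reach, smallest
#' incidence angle) and (longest reach, largest incidence angle) — finds the
#' spraying pressure at which the leaf's predicted tip descent equals the
#' parallel-to-ground threshold \eqn{l\sin\beta}. The evaluation chain for a
#' trial pressure P is: Bernoulli exit velocity, numerical inverse of the
#' travel-distance relation for the flight time, arrival speed, impact force
#' (with the spray volume per `volume_mode`), then the static tip deflection
#' in the chosen deflection `mode`.
#'
#' The root is found by bisection on log-pressure over a fixed bracket
#' (100 Pa, 10 MPa) to a residual below `tol` Pa. With
#' `volume_mode = "single_droplet"` the criterion is unreachable below
#' 10 MPa for realistic leaves — one millimetre droplet simply cannot carry
#' the required momentum — so the solver defaults to the aggregate
#' interpretation, in which the load is built up by the liquid delivered
#' over an accumulation `window` (default 5 s; see the methods vignette).
#'
#' @param geom A [leaf_geometry()].
#' @param mat A [leaf_material()].
#' @param spec A [nozzle_spec()].
#' @param droplet_radius Droplet radius (m).
#' @param G Spray self-weight (N).
#' @param mode Deflection mode passed to [deflection_profile()].
#' @param volume_mode `"aggregate"` (default) or `"single_droplet"`.
#' @param window Accumulation window for aggregate volume (s).
#' @param tilt Nozzle tilt for the ballistic chain (degrees); defaults to
#'   mid-cone, half the working cone angle.
#' @param rho Liquid density (kg/m^3).
#' @param bracket Pressure bracket (Pa) for root-finding.
#' @param tol Pressure residual tolerance (Pa).
#' @return A `pressure_window` object: list with `P_range`, `Q_range`,
#'   `endpoints` (tibble of per-endpoint chains) and the call inputs.
#'   Errors with class `leafspray_no_solution` if an endpoint's criterion is
#'   unreachable inside the bracket.
#' @examples
#' \donttest{
#' solve_operating_pressure(
#'   leaf_geometry(0.035, 0.015, 4e-4, 33.222),
#'   leaf_material(), nozzle_spec())
#' }
#' @export
solve_operating_pressure <- function(geom, mat, spec,
                                     droplet_radius = 1e-3, G = 3e-4,
                                     mode = c("literal", "beam"),
                                     volume_mode = c("aggregate", "single_droplet"),
                                     window = 5,
                                     tilt = NULL,
                                     rho = WATER_DENSITY,
                                     bracket = c(1e2, 1e7), tol = 1) {
  mode <- match.arg(mode)
  volume_mode <- match.arg(volume_mode)
  if (is.null(tilt)) tilt <- spec$gamma_rounded / 2
  target <- parallel_ground_threshold(geom)
  env <- design_envelope(spec, geom$angle)
  endpoints <- tibble(
    endpoint = c("nadir", "cone_edge"),
    lw = c(env$lw_min, env$lw_max),
    theta_t = c(env$theta_t_min, env$theta_t_max)
  )

  tip_at <- function(P, lw, theta_t) {
    v0 <- pressure_to_velocity(P, rho)
    launch <- launch_state(v0, tilt = tilt)
    t <- time_to_distance(launch, lw)
    v1 <- impact_velocity(launch, t)
    dspec <- if (volume_mode == "single_droplet") {
      droplet_spec(droplet_radius, rho, "single_droplet", self_weight = G)
    } else {
      droplet_spec(droplet_radius, rho, "aggregate",
                   flow_rate = flow_rate(spec, P, rho), window = window,
                   self_weight = G)
    }
    F0 <- impact_force(dspec, v1)
    attr(deflection_profile(geom, mat, F0, theta_t, G, mode = mode, n = 2),
         "tip_drop")
  }

  solve_one <- function(lw, theta_t, endpoint) {
    f <- function(logP) tip_at(exp(logP), lw, theta_t) - target
    lo <- log(bracket[1]); hi <- log(bracket[2])
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
      abort(sprintf(
        "parallel-to-ground criterion unreachable for endpoint '%s' within P in (%.0f Pa, %.0f Pa]",
        endpoint, bracket[1], bracket[2]),
        class = "leafspray_no_solution")
    }
    # bisection on log-pressure until the pressure residual is below tol
    repeat {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (fm * flo <= 0) hi <- mid else { lo <- mid; flo <- fm }
      if (exp(hi) - exp(lo) < tol) break
    }
    exp((lo + hi) / 2)
  }

  P <- purrr::map_dbl(seq_len(nrow(endpoints)), function(i) {
    solve_one(endpoints$lw[i], endpoints$theta_t[i], endpoints$endpoint[i])
  })
  endpoints$P <- P
  endpoints$Q <- flow_rate(spec, P, rho)
  endpoints$v0 <- pressure_to_velocity(P, rho)
  P_range <- range(P)
  structure(
    list(
      P_range = P_range,
      Q_range = range(endpoints$Q),
      endpoints = endpoints,
      target_tip_drop = target,
      mode = mode, volume_mode = volume_mode, window = window,
      tilt = tilt, geom = geom, mat = mat, spec = spec,
      droplet_radius = droplet_radius, G = G
    ),
    class = "pressure_window"
  )
}

#' @export
print.pressure_window <- function(x, ...) {
  cat(sprintf(
    "<pressure_window> P in [%.4g, %.4g] MPa, Q in [%.4g, %.4g] kg/s\n",
    x$P_range[1] / 1e6, x$P_range[2] / 1e6, x$Q_range[1], x$Q_range[2]))
  cat(sprintf("  deflection mode '%s', volume mode '%s' (window %g s), tilt %g deg\n",
              x$mode, x$volume_mode, x$window, x$tilt))
  print(x$endpoints)
  invisible(x)
}

#' @describeIn solve_operating_pressure Per-endpoint solution chain as a tibble.
#' @param x,object A `pressure_window`.
#' @param ... Unused.
#' @export
tidy.pressure_window <- function(x, ...) {
  x$endpoints
}

#' @describeIn solve_operating_pressure One-row summary of the solved window.
#' @export
glance.pressure_window <- function(x, ...) {
  tibble(
    P_min = x$P_range[1], P_max = x$P_range[2],
    Q_min = x$Q_range[1], Q_max = x$Q_range[2],
    target_tip_drop = x$target_tip_drop,
    mode = x$mode, volume_mode = x$volume_mode, window = x$window
  )
}
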