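#' Physical description of the discretized herbicide spray
#'
#' A droplet specification collects the constants needed to turn an arrival
#' velocity into an impact force: particle radius, liquid density, the volume
#' of discretized spray associated with one impact, and the self-weight of the
#' spray bearing on the leaf.
#'
#' Two conventions exist for the volume entering the impact-force law:
#'
#' * `"single_droplet"` (default): the volume of one spherical droplet,
#'   \eqn{V = \frac{4}{3}\pi R^3}. The impact force is then the force of one
#'   particle striking the leaf.
#' * `"aggregate"`: the volume of liquid delivered by the nozzle over an
#'   accumulation window \eqn{\Delta t}, \eqn{V = Q \Delta t / \rho}. This
#'   treats the quasi-static load on the leaf as built up by the whole stream
#'   rather than one droplet; it is the convention under which the
#'   parallel-to-ground deflection criterion is attainable at field-realistic
#'   pressures (see [solve_operating_pressure()]).
#'
#' @param radius Droplet radius (m). The field-measured reference value for a
#'   hydraulic nozzle at a few bar is 1 mm.
#' @param density Liquid density (kg/m^3); aqueous herbicide is water-like.
#' @param volume_mode `"single_droplet"` or `"aggregate"`.
#' @param flow_rate Nozzle mass flow (kg/s); required for `"aggregate"`.
#' @param window Accumulation window \eqn{\Delta t} (s); required for
#'   `"aggregate"`.
#' @param self_weight Self-weight G of the spray bearing on the leaf (N).
#'   Defaults to the literature value 3e-4 N rather than \eqn{\rho V g}, which
#'   would be two orders of magnitude smaller for a 1 mm droplet.
#'
#' @return A `droplet_spec` list with fields `radius`, `density`, `volume`,
#'   `volume_mode`, `self_weight`.
#' @examples
#' droplet_spec(radius = 1e-3)
#' @export
droplet_spec <- function(radius = 1e-3, density = WATER_DENSITY,
                         volume_mode = c("single_droplet", "aggregate"),
                         flow_rate = NULL, window = NULL,
                         self_weight = 3e-4) {
  volume_mode <- match.arg(volume_mode)
  check_positive(radius, "radius")
  check_positive(density, "density")
  check_nonneg(self_weight, "self_weight")
  volume <- if (volume_mode == "single_droplet") {
    4 / 3 * pi * radius^3
  } else {
    if (is.null(flow_rate) || is.null(window)) {
      stop_domain("aggregate volume mode needs `flow_rate` and `window`")
    }
    check_positive(flow_rate, "flow_rate")
    check_positive(window, "window")
    flow_rate * window / density
  }
  structure(
    list(radius = radius, density = density, volume = volume,
         volume_mode = volume_mode, self_weight = self_weight),
    class = "droplet_spec"
  )
}

#' @export
print.droplet_spec <- function(x, ...) {
  cat(sprintf(
    "<droplet_spec> R = %.3g mm, rho = %g kg/m^3, V = %.4g m^3 (%s), G = %.3g N\n",
    x$radius * 1e3, x$density, x$volume, x$volume_mode, x$self_weight))
  invisible(x)
}

#' Launch state of spray leaving the nozzle
#'
#' The spray leaves the nozzle at speed `v0` along a direction tilted by
#' `tilt` degrees from the downward vertical and then follows drag-free
#' oblique projectile motion. The velocity component along the tilt direction
#' is constant (`v0 sin(tilt)`) and the vertical component grows under
#' gravity (`v0 cos(tilt) + g t`).
#'
#' @param v0 Nozzle exit speed (m/s).
#' @param tilt Nozzle tilt angle from the downward vertical (degrees), in
#'   `[0, 90)`. Mid-cone spraying corresponds to half the cone angle.
#' @param g Gravitational acceleration (m/s^2).
#' @return A `launch_state` list.
#' @examples
#' launch_state(v0 = sqrt(2 * 0.4e6 / 1000), tilt = 17.5)
#' @export
launch_state <- function(v0, tilt = 0, g = GRAVITY) {
  check_nonneg(v0, "v0")
  check_nonneg(g, "g")
  if (!is.finite(tilt) || tilt < 0 || tilt >= 90) {
    stop_domain("`tilt` must be in [0, 90) degrees")
  }
  structure(list(v0 = v0, tilt = tilt, g = g), class = "launch_state")
}

#' @export
print.launch_state <- function(x, ...) {
  cat(sprintf("<launch_state> v0 = %.4g m/s, tilt = %g deg, g = %g m/s^2\n",
              x$v0, x$tilt, x$g))
  invisible(x)
}

#' Arrival speed of spray after a flight time
#'
#' Drag-free projectile speed at flight time `t`:
#' \deqn{v_1 = \sqrt{(v_0\sin\theta_d)^2 + (v_0\cos\theta_d + g t)^2}.}
#' Equivalent to the energy identity \eqn{v_1^2 = v_0^2 + 2 g \,\Delta z}
#' with \eqn{\Delta z} the vertical descent during flight.
#'
#' @param launch A [launch_state()].
#' @param t Flight time(s) in seconds; vectorized.
#' @return Arrival speed v1 (m/s).
#' @examples
#' impact_velocity(launch_state(28.2843, tilt = 35), t = 0.012)
#' @export
impact_velocity <- function(launch, t) {
  check_nonneg(t, "t")
  td <- deg2rad(launch$tilt)
  sqrt((launch$v0 * sin(td))^2 + (launch$v0 * cos(td) + launch$g * t)^2)
}

#' Straight-line travel distance after a flight time
#'
#' Distance from the nozzle to the spray's position at flight time `t`:
#' \deqn{l_w = \sqrt{(v_0 t\sin\theta_d)^2 +
#'   (v_0 t\cos\theta_d + \tfrac12 g t^2)^2},}
#' strictly increasing in `t` whenever `v0 > 0` or `g > 0`.
#'
#' @inheritParams impact_velocity
#' @return Travel distance lw (m).
#' @examples
#' travel_distance(launch_state(28.2843, tilt = 35), t = 0.012)
#' @export
travel_distance <- function(launch, t) {
  check_nonneg(t, "t")
  td <- deg2rad(launch$tilt)
  sqrt((launch$v0 * t * sin(td))^2 +
         (launch$v0 * t * cos(td) + 0.5 * launch$g * t^2)^2)
}

#' Vertical descent during flight
#'
#' @inheritParams impact_velocity
#' @return Vertical drop height (m) after flight time `t`.
#' @export
drop_height <- function(launch, t) {
  check_nonneg(t, "t")
  launch$v0 * t * cos(deg2rad(launch$tilt)) + 0.5 * launch$g * t^2
}

#' Flight time to reach a given travel distance
#'
#' Numerical inverse of [travel_distance()]. The distance is strictly
#' increasing in time (for `v0 > 0` or `g > 0`), so the root is unique; it is
#' found by bracketed root-finding to an absolute distance residual below
#' 1e-9 m.
#'
#' @inheritParams impact_velocity
#' @param lw_target Target straight-line distance (m).
#' @return Flight time t (s).
#' @examples
#' time_to_distance(launch_state(28.2843, tilt = 35), lw_target = 0.34)
#' @export
time_to_distance <- function(launch, lw_target) {
  check_nonneg(lw_target, "lw_target")
  if (lw_target == 0) return(0)
  if (launch$v0 == 0 && launch$g == 0) {
    stop_domain("distance unreachable: v0 = 0 and g = 0")
  }
  # upper bracket: time ignoring gravity plus free-fall bound
  t_hi <- if (launch$v0 > 0) lw_target / launch$v0 else 0
  t_hi <- max(t_hi, sqrt(2 * lw_target / max(launch$g, 1e-12)))
  while (travel_distance(launch, t_hi) < lw_target) t_hi <- t_hi * 2
  uniroot(function(t) travel_distance(launch, t) - lw_target,
          lower = 0, upper = t_hi, tol = 1e-13)$root
}

#' Impact force of the discretized spray on a leaf
#'
#' \deqn{F_0 = \frac{\pi \rho R v_1^2 V}{2},} quadratic in the arrival speed,
#' with R the particle radius, \eqn{\rho} the liquid density and V the spray
#' volume per the droplet spec's `volume_mode`.
#'
#' @param spec A [droplet_spec()].
#' @param v1 Arrival speed(s) at the leaf (m/s); vectorized.
#' @return Impact force F0 (N).
#' @examples
#' impact_force(droplet_spec(1e-3), v1 = 28.381)
#' @export
impact_force <- function(spec, v1) {
  check_nonneg(v1, "v1")
  pi * spec$density * spec$radius * v1^2 * spec$volume / 2
}

#' Full kinematic state of spray on arrival at the leaf
#'
#' Chains the projectile relations: inverts the travel distance for the
#' flight time, evaluates the arrival speed and the impact force.
#'
#' @inheritParams impact_force
#' @inheritParams time_to_distance
#' @return A one-row tibble with `t`, `v1`, `lw`, `drop_height`, `F0`.
#' @examples
#' impact_kinematics(droplet_spec(1e-3), launch_state(28.2843, 17.5), 0.3)
#' @export
impact_kinematics <- function(spec, launch, lw_target) {
  t <- time_to_distance(launch, lw_target)
  v1 <- impact_velocity(launch, t)
  tibble(
    t = t, v1 = v1, lw = travel_distance(launch, t),
    drop_height = drop_height(launch, t),
    F0 = impact_force(spec, v1)
  )
}
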