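#' Cantilever-beam idealization of a weed leaf
#'
#' A leaf is treated as a uniform rectangular-section cantilever clamped at
#' the stem: length `l`, maximum width `b`, thickness `hl`, inclined at the
#' leaf angle `beta` above the horizontal. The angle between leaf and stem is
#' `theta = 90 - beta` and the blade area is `A = b * l`. Taper is not
#' modelled.
#'
#' @param length Leaf length l (m).
#' @param width Maximum leaf width b (m).
#' @param thickness Leaf thickness hl (m).
#' @param angle Leaf angle beta above the horizontal (degrees), in (0, 90).
#' @return A `leaf_geometry` list with derived `theta` (degrees), `area`
#'   (m^2) and second moment of area `inertia` (m^4).
#' @examples
#' leaf_geometry(0.035, 0.015, 4e-4, 33.222)
#' @export
leaf_geometry <- function(length, width, thickness, angle) {
  check_positive(length, "length")
  check_positive(width, "width")
  check_positive(thickness, "thickness")
  if (!is.finite(angle) || angle <= 0 || angle >= 90) {
    stop_domain("`angle` (leaf angle beta) must be in (0, 90) degrees")
  }
  structure(
    list(length = length, width = width, thickness = thickness,
         angle = angle, theta = 90 - angle, area = width * length,
         inertia = width * thickness^3 / 12),
    class = "leaf_geometry"
  )
}

#' @export
print.leaf_geometry <- function(x, ...) {
  cat(sprintf(
    "<leaf_geometry> l = %g mm, b = %g mm, hl = %g mm, beta = %g deg (theta = %g deg)\n",
    x$length * 1e3, x$width * 1e3, x$thickness * 1e3, x$angle, x$theta))
  invisible(x)
}

#' Leaf material properties
#'
#' Two elastic-modulus presets are in circulation for the target weed:
#' 272.5 MPa (literature value used by the static deflection model) and
#' 222.85 MPa (the plant-template measurement set). They are not reconciled;
#' both are exposed and the choice is explicit.
#'
#' @param E Elastic modulus (Pa). Default 272.5 MPa.
#' @param density Tissue density (kg/m^3). Default 700.
#' @return A `leaf_material` list.
#' @examples
#' leaf_material()                 # 272.5 MPa preset
#' leaf_material(E = 222.85e6)     # plant-template preset
#' @export
leaf_material <- function(E = 272.5e6, density = 700) {
  check_positive(E, "E")
  check_positive(density, "density")
  structure(list(E = E, density = density), class = "leaf_material")
}

#' @export
print.leaf_material <- function(x, ...) {
  cat(sprintf("<leaf_material> E = %g MPa, density = %g kg/m^3\n",
              x$E / 1e6, x$density))
  invisible(x)
}

#' Cross-sectional moment of inertia of the leaf blade
#'
#' \deqn{I = b\,h_l^3/12} for the rectangular section.
#'
#' @param geom A [leaf_geometry()].
#' @return I (m^4).
#' @export
section_inertia <- function(geom) {
  geom$width * geom$thickness^3 / 12
}

#' Effective transverse surface load on the leaf
#'
#' Combines the spray impact force and the spray self-weight into one
#' equivalent surface load, with the projection factors of the bending-moment
#' integrand: \deqn{q = \frac{F_0\sin\theta\cos\theta_t + G\cos\beta}
#' {A\cos^2\theta}} where \eqn{\theta} is the leaf-stem angle,
#' \eqn{\theta_t} the incidence angle between spray and leaf normal and
#' \eqn{\beta} the leaf angle.
#'
#' @param F0 Impact force (N).
#' @param geom A [leaf_geometry()].
#' @param theta_t Spray incidence angle (degrees).
#' @param G Spray self-weight (N).
#' @return Surface load q (N/m^2).
#' @examples
#' g <- leaf_geometry(0.035, 0.015, 4e-4, 33.222)
#' load_intensity(5.3e-6, g, theta_t = 50, G = 3e-4)
#' @export
load_intensity <- function(F0, geom, theta_t, G) {
  check_nonneg(F0, "F0")
  check_nonneg(G, "G")
  th <- deg2rad(geom$theta)
  if (abs(cos(th)) < 1e-12) {
    stop_domain("singular configuration: leaf-stem angle theta = 90 degrees")
  }
  (F0 * sin(th) * cos(deg2rad(theta_t)) + G * cos(deg2rad(geom$angle))) /
    (geom$area * cos(th)^2)
}

#' Static deflection profile of a leaf under spray load
#'
#' Computes the transverse deflection y(x) of the cantilevered leaf under the
#' spray impact force `F0` and self-weight `G`, in two interpretations:
#'
#' * `mode = "literal"` evaluates the published closed form of the deflection
#'   model with its double integral read as the integrand at the full blade
#'   dimensions multiplied by the blade area (the integral diverges if taken
#'   verbatim, since the integrand carries the dimensions in its
#'   denominator). The load-induced part is
#'   \deqn{y_F(x) = \frac{\pi\rho v_1^2 R V \sin\theta\cos\theta_t\, x^4 +
#'     G\cos\beta\, x^2}{4 E b h_l^3 \cos^2\theta}
#'     = \frac{2F_0 \sin\theta\cos\theta_t\, x^4 + G\cos\beta\, x^2}
#'     {4 E b h_l^3 \cos^2\theta}.}
#' * `mode = "beam"` is the textbook Euler-Bernoulli cantilever under the
#'   uniformly distributed line load \eqn{w = q b} from [load_intensity()]:
#'   \deqn{y_F(x) = \frac{w x^2}{24 E I}(x^2 - 4 l x + 6 l^2),} with tip
#'   deflection \eqn{w l^4 / (8 E I)}.
#'
#' Both modes add the rigid inclination term \eqn{\theta x} (theta in
#' radians) so that the zero-load profile is the undeformed inclined leaf in
#' the model's small-angle frame. The attribute `tip_drop` is the
#' load-induced deflection at the tip, the quantity compared against
#' [parallel_ground_threshold()]; `mode_ratio` is the literal/beam tip ratio
#' at the same inputs.
#'
#' @inheritParams load_intensity
#' @param mat A [leaf_material()].
#' @param mode `"literal"` (default) or `"beam"`.
#' @param n Number of points along the leaf.
#' @return A tibble of class `deflection_profile` with columns `x`, `y`,
#'   `y_load` (m) and attributes `tip_drop`, `mode`, `mode_ratio`, `C1`
#'   (= theta, radians), `C2` (= 0).
#' @examples
#' g <- leaf_geometry(0.035, 0.015, 4e-4, 33.222)
#' m <- leaf_material()
#' p <- deflection_profile(g, m, F0 = 5.3e-6, theta_t = 50, G = 3e-4)
#' attr(p, "tip_drop")
#' @export
deflection_profile <- function(geom, mat, F0, theta_t, G,
                               mode = c("literal", "beam"), n = 101) {
  mode <- match.arg(mode)
  check_nonneg(F0, "F0")
  check_nonneg(G, "G")
  th <- deg2rad(geom$theta)
  if (abs(cos(th)) < 1e-12) {
    stop_domain("singular configuration: leaf-stem angle theta = 90 degrees")
  }
  x <- seq(0, geom$length, length.out = n)
  y_literal <- function(x) {
    (2 * F0 * sin(th) * cos(deg2rad(theta_t)) * x^4 +
       G * cos(deg2rad(geom$angle)) * x^2) /
      (4 * mat$E * geom$width * geom$thickness^3 * cos(th)^2)
  }
  y_beam <- function(x) {
    w <- load_intensity(F0, geom, theta_t, G) * geom$width
    w * x^2 * (x^2 - 4 * geom$length * x + 6 * geom$length^2) /
      (24 * mat$E * section_inertia(geom))
  }
  y_load <- switch(mode, literal = y_literal(x), beam = y_beam(x))
  tip_lit <- y_literal(geom$length)
  tip_beam <- y_beam(geom$length)
  out <- tibble(x = x, y_load = y_load, y = th * x + y_load)
  structure(
    out,
    class = c("deflection_profile", class(out)),
    tip_drop = if (mode == "literal") tip_lit else tip_beam,
    mode = mode,
    mode_ratio = if (tip_beam > 0) tip_lit / tip_beam else NA_real_,
    C1 = th, C2 = 0
  )
}

#' @export
autoplot.deflection_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$x * 1e3)) +
    geom_line(aes(y = .data$y * 1e3, colour = "deflected")) +
    geom_line(aes(y = attr(object, "C1") * .data$x * 1e3,
                  colour = "undeformed"), linetype = 2) +
    labs(x = "position along leaf (mm)", y = "profile y (mm)",
         colour = NULL,
         title = sprintf("Leaf deflection (%s mode)", attr(object, "mode")))
}

#' Tip descent that brings the leaf parallel to the ground
#'
#' A straight leaf inclined at `beta` becomes horizontal when its tip
#' descends by \eqn{l\sin\beta}. This is the deflection at which herbicide
#' retention is maximal; beyond it the interaction enters the strong-impact
#' and drainage regime.
#'
#' @param geom A [leaf_geometry()].
#' @return Critical tip descent (m).
#' @examples
#' parallel_ground_threshold(leaf_geometry(0.035, 0.015, 4e-4, 33.22))
#' @export
parallel_ground_threshold <- function(geom) {
  geom$length * sin(deg2rad(geom$angle))
}

#' Leaf deformation index
#'
#' \deqn{\xi = \Delta x / x_i = (x_d - x_i)/x_i,} the relative increase of
#' the leaf's extent along the ground axis between the initial state
#' (`xi`) and the deformed state (`xd`). Positive when the leaf flattens
#' toward the ground.
#'
#' @param xi Initial along-ground extent of the leaf (m); must be positive.
#' @param xd Deformed along-ground extent (m).
#' @return Dimensionless deformation index.
#' @examples
#' deformation_index(xi = 29.28e-3, xd = (29.28 + 12.50) * 1e-3)
#' @export
deformation_index <- function(xi, xd) {
  check_positive(xi, "xi")
  (xd - xi) / xi
}

#' Deformation index of a rigid leaf given its tip descent
#'
#' Maps a vertical tip descent to the deformation index through the
#' rigid-rotation frame: a straight leaf of length l at angle beta whose tip
#' drops by `tip_drop` takes the new angle
#' \eqn{\beta' = \arcsin(\sin\beta - \mathrm{tip\_drop}/l)} and extends to
#' \eqn{x_d = l\cos\beta'}, so \eqn{\xi = \cos\beta'/\cos\beta - 1}. The
#' index is capped at the inextensible ceiling \eqn{1/\cos\beta - 1},
#' attained when the leaf is parallel to the ground.
#'
#' @param geom A [leaf_geometry()].
#' @param tip_drop Vertical tip descent (m); vectorized.
#' @return Deformation index xi.
#' @export
rigid_deformation_index <- function(geom, tip_drop) {
  check_nonneg(tip_drop, "tip_drop")
  beta <- deg2rad(geom$angle)
  s <- pmax(pmin(sin(beta) - tip_drop / geom$length, 1), 0)
  cos(asin(s)) / cos(beta) - 1
}
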