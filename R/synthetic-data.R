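# Synthetic inputs: parameterized weed plants, droplet streams, and (in
# stain-image.R) water-sensitive-paper stain images. Everything the pipeline
# consumes can be generated from printed parameters; no downloads.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Template for an A. retroflexus-like weed plant
#'
#' Mean measured parameters of the two-layer, twelve-leaf broadleaf weed
#' used throughout: plant height 35 mm, leaf angle 33.222 degrees, leaf
#' thickness 0.4 mm, bottom leaves 35 x 15 mm, top leaves 20 x 8 mm, stem
#' diameter 3 mm, tissue density 700 kg/m^3. The elastic modulus defaults
#' to the template measurement set (222.85 MPa); the alternative literature
#' preset is 272.5 MPa.
#'
#' @param height Plant height (m).
#' @param n_leaves Total number of leaves.
#' @param n_top Number of top-layer leaves.
#' @param leaf_angle Leaf angle beta (degrees).
#' @param thickness Leaf thickness (m).
#' @param bottom_length,bottom_width Bottom-leaf blade dimensions (m).
#' @param top_length,top_width Top-leaf blade dimensions (m).
#' @param stem_diameter Stem diameter (m).
#' @param density Leaf tissue density (kg/m^3).
#' @param E Elastic modulus (Pa).
#' @return A `plant_template` list.
#' @examples
#' plant_template()
#' @export
plant_template <- function(height = 35e-3, n_leaves = 12L, n_top = 4L,
                           leaf_angle = 33.222, thickness = 0.4e-3,
                           bottom_length = 35e-3, bottom_width = 15e-3,
                           top_length = 20e-3, top_width = 8e-3,
                           stem_diameter = 3e-3, density = 700,
                           E = 222.85e6) {
  stopifnot(n_top < n_leaves)
  structure(
    list(height = height, n_leaves = as.integer(n_leaves),
         n_top = as.integer(n_top), leaf_angle = leaf_angle,
         thickness = thickness, bottom_length = bottom_length,
         bottom_width = bottom_width, top_length = top_length,
         top_width = top_width, stem_diameter = stem_diameter,
         density = density, E = E),
    class = "plant_template"
  )
}

#' Build a plant geometry from a template
#'
#' Positions the leaves on a vertical stem in two layers: the bottom layer
#' (`n_leaves - n_top` leaves, azimuths every 45 degrees starting at 0) at
#' 40% of the plant height and the top layer (`n_top` leaves, azimuths
#' every 90 degrees starting at 45, i.e. offset 45 degrees from the bottom
#' growth directions) at the top of the stem. Each leaf carries its
#' cantilever geometry and the lumped modal parameters of [modal_leaf()].
#'
#' With `jitter > 0`, leaf lengths, widths, thicknesses and angles are
#' perturbed by independent multiplicative uniform noise on
#' `[1 - jitter, 1 + jitter]`; `jitter = 0` reproduces the template
#' exactly. Deterministic for a fixed seed.
#'
#' @param template A [plant_template()].
#' @param jitter Multiplicative jitter fraction in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param damping_ratio Modal damping ratio for every leaf.
#' @return A `weed_plant` list with a `leaves` tibble (positions, angles,
#'   blade dimensions, modal `M`, `C`, `K`, the parallel-to-ground tip
#'   threshold and deformation-index ceiling `xi_parallel`) and the
#'   template.
#' @examples
#' plant <- build_plant(plant_template())
#' plant$leaves
#' @export
build_plant <- function(template = plant_template(), jitter = 0, seed = 1,
                        damping_ratio = 0.05) {
  if (!is.finite(jitter) || jitter < 0 || jitter >= 0.5) {
    stop_domain("`jitter` must be in [0, 0.5)")
  }
  n_bottom <- template$n_leaves - template$n_top
  layer <- c(rep("bottom", n_bottom), rep("top", template$n_top))
  azimuth <- c((seq_len(n_bottom) - 1) * 360 / n_bottom,
               45 + (seq_len(template$n_top) - 1) * 360 / template$n_top)
  attach_z <- c(rep(0.4 * template$height, n_bottom),
                rep(template$height, template$n_top))
  len <- ifelse(layer == "bottom", template$bottom_length, template$top_length)
  wid <- ifelse(layer == "bottom", template$bottom_width, template$top_width)
  thick <- rep(template$thickness, template$n_leaves)
  beta <- rep(template$leaf_angle, template$n_leaves)
  if (jitter > 0) {
    noise <- with_seed(seed, matrix(runif(4 * template$n_leaves,
                                          1 - jitter, 1 + jitter),
                                    ncol = 4))
    len <- len * noise[, 1]; wid <- wid * noise[, 2]
    thick <- thick * noise[, 3]; beta <- pmin(beta * noise[, 4], 89)
  }
  r_stem <- template$stem_diameter / 2
  mat <- leaf_material(E = template$E, density = template$density)
  leaves <- purrr::map(seq_len(template$n_leaves), function(i) {
    geom <- leaf_geometry(len[i], wid[i], thick[i], beta[i])
    ml <- modal_leaf(geom, mat,
                     position = c(r_stem * cos(deg2rad(azimuth[i])),
                                  r_stem * sin(deg2rad(azimuth[i])),
                                  attach_z[i]),
                     azimuth = azimuth[i],
                     damping_ratio = damping_ratio, id = i)
    xi_par <- 1 / cos(deg2rad(beta[i])) - 1
    tibble(
      leaf = i, layer = layer[i], azimuth = azimuth[i],
      attach_x = ml$position[1], attach_y = ml$position[2],
      attach_z = ml$position[3],
      length = len[i], width = wid[i], thickness = thick[i], beta = beta[i],
      M = ml$M, C = ml$C, K = ml$K,
      tip_threshold = parallel_ground_threshold(geom),
      xi_parallel = xi_par
    )
  })
  structure(
    list(leaves = dplyr::bind_rows(leaves), template = template,
         material = mat, damping_ratio = damping_ratio,
         jitter = jitter, seed = as.integer(seed)),
    class = "weed_plant"
  )
}

#' @export
print.weed_plant <- function(x, ...) {
  cat(sprintf("<weed_plant> %d leaves (%d bottom + %d top), height %g mm, E = %g MPa\n",
              nrow(x$leaves), sum(x$leaves$layer == "bottom"),
              sum(x$leaves$layer == "top"),
              x$template$height * 1e3, x$material$E / 1e6))
  invisible(x)
}

#' Nozzle operating point
#'
#' Bundles a spraying pressure with its Bernoulli exit velocity and
#' discharge mass flow for a given nozzle.
#'
#' @param P Spraying (gauge) pressure (Pa).
#' @param nozzle A [nozzle_spec()].
#' @param rho Liquid density (kg/m^3).
#' @return An `operating_point` list with `P`, `dP`, `v0`, `Q`, `A1`,
#'   `nozzle`, `rho`.
#' @examples
#' operating_point(0.4e6)
#' @export
operating_point <- function(P, nozzle = nozzle_spec(), rho = WATER_DENSITY) {
  check_nonneg(P, "P")
  structure(
    list(P = P, dP = P, v0 = pressure_to_velocity(P, rho),
         Q = flow_rate(nozzle, P, rho), A1 = nozzle$A1,
         nozzle = nozzle, rho = rho),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> P = %.4g MPa, v0 = %.4g m/s, Q = %.4g kg/s\n",
              x$P / 1e6, x$v0, x$Q))
  invisible(x)
}

#' Sample a droplet stream consistent with an operating point
#'
#' Emits droplets from the nozzle position at the Bernoulli exit speed,
#' with directions uniform in solid angle inside the spray cone and
#' emission times regular over the duration. The droplet count is
#' `round(Q * duration / droplet mass)`, so the emitted mass rate matches
#' the nozzle flow to within one droplet. Deterministic for a fixed seed.
#'
#' @param op An [operating_point()].
#' @param droplet A [droplet_spec()]; its radius and density set the
#'   per-droplet mass.
#' @param duration Emission duration (s).
#' @param seed Integer seed (directions only; times are regular).
#' @param nozzle_position Emission point (m); defaults to the nozzle's
#'   ground clearance on the plant axis.
#' @param cone Cone half-angle (degrees); defaults to the nozzle's working
#'   cone angle.
#' @return A `droplet_stream` tibble: `id`, `time` (s), `x`, `y`, `z` (m),
#'   `vx`, `vy`, `vz` (m/s), `radius` (m), `mass` (kg).
#' @examples
#' sample_droplets(operating_point(0.4e6), droplet_spec(), duration = 0.01)
#' @export
sample_droplets <- function(op, droplet = droplet_spec(), duration = 0.5,
                            seed = 1, nozzle_position = NULL, cone = NULL) {
  check_nonneg(duration, "duration")
  if (is.null(nozzle_position)) nozzle_position <- c(0, 0, op$nozzle$height)
  if (is.null(cone)) cone <- op$nozzle$gamma_rounded
  m_drop <- droplet$density * 4 / 3 * pi * droplet$radius^3
  n <- round(op$Q * duration / m_drop)
  if (duration == 0 || n == 0) {
    out <- tibble(id = integer(), time = double(), x = double(),
                  y = double(), z = double(), vx = double(), vy = double(),
                  vz = double(), radius = double(), mass = double())
    return(structure(out, class = c("droplet_stream", class(out)),
                     Q_target = op$Q, cone = cone))
  }
  dirs <- with_seed(seed, {
    cosphi <- runif(n, cos(deg2rad(cone)), 1)
    alpha <- runif(n, 0, 2 * pi)
    sinphi <- sqrt(1 - cosphi^2)
    cbind(sinphi * cos(alpha), sinphi * sin(alpha), -cosphi)
  })
  out <- tibble(
    id = seq_len(n),
    time = (seq_len(n) - 0.5) / n * duration,
    x = nozzle_position[1], y = nozzle_position[2], z = nozzle_position[3],
    vx = op$v0 * dirs[, 1], vy = op$v0 * dirs[, 2], vz = op$v0 * dirs[, 3],
    radius = droplet$radius, mass = m_drop
  )
  structure(out, class = c("droplet_stream", class(out)),
            Q_target = op$Q, cone = cone)
}
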