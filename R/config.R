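# Run configuration shared by the command-line entry points. SI units
# throughout (m, s, Pa, kg); exports use mm / MPa where conventional.

.config_defaults <- function() {
  list(
    # physical constants
    g = 9.8, rho = 1000, air_density = 1.225, air_viscosity = 1.7894e-5,
    # nozzle
    outlet_radius = 5e-4, discharge_coef = 0.6, height = 0.3,
    lateral_range = 0.2, P = 0.4e6,
    # droplet / spray
    droplet_radius = 1e-3, self_weight = 3e-4,
    volume_mode = "aggregate", window = 5,
    # leaf (static model)
    leaf_length = 0.035, leaf_width = 0.015, leaf_thickness = 4e-4,
    leaf_angle = 33.222, E = 272.5e6, deflection_mode = "literal",
    # plant template (simulation)
    E_plant = 222.85e6, leaf_density = 700, jitter = 0,
    damping_ratio = 0.05,
    # simulation
    dt = 0.001, duration = 0.5, restitution = 0.3, splash_threshold = 15,
    rebound_cutoff = 1, film_response_time = 0.02,
    # coverage / rendering
    resolution = 2.5e-4, spread_factor = 2,
    target_test = 0.16, target_control_left = 0.72,
    target_control_right = 0.68,
    seed = 1
  )
}

#' Assemble a run configuration
#'
#' All physical constants and mode switches with their reference defaults;
#' any subset may be overridden by name. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list.
#' @examples
#' run_config(P = 0.5e6, seed = 42)
#' @export
run_config <- function(...) {
  overrides <- list(...)
  defaults <- .config_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0 || (length(overrides) > 0 &&
                              (is.null(names(overrides)) ||
                                 any(names(overrides) == "")))) {
    stop_domain(paste0("unknown config key(s): ",
                       paste(unknown, collapse = ", ")))
  }
  structure(modifyList(defaults, overrides), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' The write -> read -> write round trip is byte-identical.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Constructors from a config -------------------------------------------------

config_nozzle <- function(cfg) {
  nozzle_spec(outlet_radius = cfg$outlet_radius,
              discharge_coef = cfg$discharge_coef,
              height = cfg$height, lateral_range = cfg$lateral_range)
}

config_leaf <- function(cfg) {
  leaf_geometry(cfg$leaf_length, cfg$leaf_width, cfg$leaf_thickness,
                cfg$leaf_angle)
}

config_sim <- function(cfg) {
  sim_config(dt = cfg$dt, duration = cfg$duration,
             air_density = cfg$air_density,
             air_viscosity = cfg$air_viscosity, seed = cfg$seed,
             restitution = cfg$restitution,
             splash_threshold = cfg$splash_threshold,
             rebound_cutoff = cfg$rebound_cutoff,
             film_response_time = cfg$film_response_time)
}
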