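# Time-domain driver coupling the particle, film and modal-leaf pieces.

# cantilever first-mode shape, tip-normalized; weights a point load at
# relative position u into the tip-equivalent coordinate
.mode_shape <- function(u) (3 * u^2 - u^3) / 2

# core segment-crossing detection shared with detect_impacts()
.detect_core <- function(p0m, p1m, velm, frames) {
  n_act <- nrow(p0m)
  best_frac <- rep(Inf, n_act)
  best <- vector("list", n_act)
  for (li in seq_along(frames)) {
    f <- frames[[li]]
    d0 <- (p0m[, 1] - f$p0[1]) * f$n[1] + (p0m[, 2] - f$p0[2]) * f$n[2] +
      (p0m[, 3] - f$p0[3]) * f$n[3]
    d1 <- (p1m[, 1] - f$p0[1]) * f$n[1] + (p1m[, 2] - f$p0[2]) * f$n[2] +
      (p1m[, 3] - f$p0[3]) * f$n[3]
    cross <- which(d0 > 0 & d1 <= 0)
    if (length(cross) == 0) next
    frac <- d0[cross] / (d0[cross] - d1[cross])
    pt <- p0m[cross, , drop = FALSE] +
      (p1m[cross, , drop = FALSE] - p0m[cross, , drop = FALSE]) * frac
    rel <- sweep(pt, 2, f$p0)
    su <- drop(rel %*% f$u)
    sw <- drop(rel %*% f$w)
    ok <- su >= 0 & su <= f$length & abs(sw) <= f$width / 2
    if (!any(ok)) next
    hit <- cross[ok]
    vn <- -drop(velm[hit, , drop = FALSE] %*% f$n)
    fr <- frac[ok]
    for (k in seq_along(hit)) {
      i <- hit[k]
      if (fr[k] < best_frac[i]) {
        best_frac[i] <- fr[k]
        best[[i]] <- list(leaf = li, s_along = su[ok][k],
                          s_across = sw[ok][k], v_normal = vn[k],
                          point = pt[ok, , drop = FALSE][k, ])
      }
    }
  }
  list(frac = best_frac, best = best)
}

#' Run the reduced-order spray-plant interaction simulation
#'
#' Couples three pieces over a fixed time grid: (i) discrete droplet
#' transport by [particle_step()] inside a constant downward jet within the
#' spray cone and still air outside it; (ii) impact detection against the
#' plant's leaf patches, with deposit / rebound / splash partitioning by
#' restitution and normal-speed thresholds; (iii) per-leaf wall-film growth
#' and one-mode structural dynamics by [leaf_step()], loaded by the
#' film-relaxed droplet momentum flux plus the accumulated film weight.
#' Leaf tip descent is mapped to the deformation index through
#' [rigid_deformation_index()], and the run is staged by
#' [classify_stage()].
#'
#' The mass ledger partitions the sprayed mass among
#' airborne / deposited / rebounded / splashed / ground / escaped at every
#' step; conservation is exact by construction and auditable from the
#' returned ledger.
#'
#' @param plant A [build_plant()] plant.
#' @param op An [operating_point()].
#' @param config A [sim_config()].
#' @param droplet A [droplet_spec()] describing the emitted droplets.
#' @return A `spray_sim` object: `trace` (tibble: time, leaf, tip_drop,
#'   xi), `stage_timeline` (tibble: time, stage), `ledger` (per-step mass
#'   accounting, kg), `ground_hits` (tibble of ground deposition points),
#'   `films` (per-leaf [wall_film()]s), `n_droplets`, and the inputs.
#' @examples
#' \donttest{
#' plant <- build_plant()
#' sim <- run_simulation(plant, operating_point(0.4e6),
#'                       sim_config(duration = 0.05, seed = 1))
#' glance(sim)
#' }
#' @export
run_simulation <- function(plant, op, config = sim_config(),
                           droplet = droplet_spec()) {
  dt <- config$dt
  nsteps <- floor(config$duration / dt + 1e-9)
  lv <- plant$leaves
  nl <- nrow(lv)
  frames <- .leaf_frames(plant)
  leaves <- purrr::map(seq_len(nl), function(i) {
    geom <- leaf_geometry(lv$length[i], lv$width[i], lv$thickness[i],
                          lv$beta[i])
    modal_leaf(geom, plant$material,
               position = c(lv$attach_x[i], lv$attach_y[i], lv$attach_z[i]),
               azimuth = lv$azimuth[i],
               damping_ratio = plant$damping_ratio, id = lv$leaf[i])
  })
  films <- purrr::map(leaves, function(l) {
    wall_film(l$geom, curvature_radius = droplet$radius,
              spread_radius = 2 * droplet$radius)
  })
  geoms <- purrr::map(leaves, "geom")

  stream <- sample_droplets(op, droplet, duration = config$duration,
                            seed = config$seed)
  n <- nrow(stream)
  empty_trace <- tibble(time = double(), leaf = integer(),
                        tip_drop = double(), xi = double())
  if (nsteps == 0) {
    return(structure(
      list(trace = empty_trace,
           stage_timeline = tibble(time = double(),
                                   stage = factor(character(),
                                                  levels = levels(classify_stage(
                                                    tibble(impacts_cum = integer(),
                                                           xi_frac = double(),
                                                           drop_frac = double()))))),
           ledger = tibble(), ground_hits = tibble(x = double(), y = double(),
                                                   mass = double()),
           films = films, n_droplets = n, plant = plant, op = op,
           config = config, droplet = droplet),
      class = "spray_sim"))
  }

  pos <- as.matrix(stream[, c("x", "y", "z")])
  vel <- as.matrix(stream[, c("vx", "vy", "vz")])
  mass <- stream$mass
  trel <- rep(stokes_relaxation_time(droplet$density, 2 * droplet$radius,
                                     config$air_viscosity), max(n, 1))
  # states: 0 pending, 1 airborne, 2 deposited, 3 rebounded, 4 splashed,
  #         5 ground, 6 escaped
  state <- rep(0L, n)
  emit <- stream$time
  jet <- if (is.null(config$jet_speed)) op$v0 else config$jet_speed
  nozzle_pos <- c(0, 0, op$nozzle$height)
  tan_cone <- tan(deg2rad(op$nozzle$gamma_rounded))
  half <- config$domain / 2

  F_imp <- rep(0, nl)        # film-relaxed impact force per leaf
  tau <- config$film_response_time
  xi_mat <- matrix(0, nsteps, nl)
  drop_mat <- matrix(0, nsteps, nl)
  ledger <- matrix(0, nsteps, 8)
  colnames(ledger) <- c("sprayed", "airborne", "deposited", "rebounded",
                        "splashed", "ground", "escaped", "pending")
  impacts_cum <- 0L
  hist_imp <- integer(nsteps)
  ground_x <- double(0); ground_y <- double(0); ground_m <- double(0)

  for (k in seq_len(nsteps)) {
    t0 <- (k - 1) * dt
    state[state == 0L & emit <= t0 + dt] <- 1L
    act <- which(state %in% c(1L, 3L, 4L))
    if (length(act) > 0) {
      spd <- sqrt(rowSums(vel[act, , drop = FALSE]^2))
      if (any(spd * dt > max(config$domain))) {
        stop_domain("step-size error: a particle moves more than one domain length per step")
      }
      # continuous phase: downward jet inside the cone, still air outside
      rel <- sweep(pos[act, , drop = FALSE], 2, nozzle_pos)
      inside <- rel[, 3] < 0 &
        sqrt(rel[, 1]^2 + rel[, 2]^2) <= -rel[, 3] * tan_cone
      vcm <- matrix(0, length(act), 3)
      vcm[inside, 3] <- -jet
      upd <- .particle_step_mat(pos[act, , drop = FALSE],
                                vel[act, , drop = FALSE],
                                vcm, trel[act], dt,
                                droplet$density, config$air_density, GRAVITY)
      det <- .detect_core(pos[act, , drop = FALSE], upd$pos,
                          upd$vel, frames)
      imp_J <- rep(0, nl) # modal impulse gathered this step
      for (ai in seq_along(act)) {
        i <- act[ai]
        ev <- det$best[[ai]]
        if (!is.null(ev)) {
          impacts_cum <- impacts_cum + 1L
          li <- ev$leaf
          phi <- .mode_shape(ev$s_along / frames[[li]]$length)
          vn <- max(ev$v_normal, 0)
          first_hit <- state[i] == 1L
          outcome <- if (!first_hit) "deposit"
          else if (vn > config$splash_threshold) "splash"
          else if (vn > config$rebound_cutoff) "rebound"
          else "deposit"
          if (outcome == "deposit") {
            state[i] <- 2L
            pos[i, ] <- ev$point
            vel[i, ] <- 0
            films[[li]] <- film_update(
              films[[li]],
              tibble(s_along = ev$s_along, s_across = ev$s_across,
                     volume = mass[i] / droplet$density))
            imp_J[li] <- imp_J[li] + mass[i] * vn * phi
          } else {
            e <- config$restitution
            nrm <- frames[[li]]$n
            v_in <- upd$vel[ai, ]
            v_out <- v_in - (1 + e) * sum(v_in * nrm) * nrm
            state[i] <- if (outcome == "splash") 4L else 3L
            pos[i, ] <- ev$point + nrm * 1e-6
            vel[i, ] <- v_out
            imp_J[li] <- imp_J[li] + mass[i] * vn * (1 + e) * phi
          }
        } else {
          pos[i, ] <- upd$pos[ai, ]
          vel[i, ] <- upd$vel[ai, ]
          if (pos[i, 3] <= 0) {
            state[i] <- 5L
            ground_x <- c(ground_x, pos[i, 1])
            ground_y <- c(ground_y, pos[i, 2])
            ground_m <- c(ground_m, mass[i])
          } else if (abs(pos[i, 1]) > half[1] || abs(pos[i, 2]) > half[2] ||
                       pos[i, 3] > config$domain[3]) {
            state[i] <- 6L
          }
        }
      }
      # film-mediated load transfer: impulses relax in with time constant tau
      F_imp <- F_imp * exp(-dt / tau) + imp_J / tau
    } else {
      F_imp <- F_imp * exp(-dt / tau)
    }
    for (li in seq_len(nl)) {
      W <- droplet$density * film_volume(films[[li]]) * GRAVITY * 3 / 8
      leaves[[li]] <- leaf_step(leaves[[li]], F_imp[li] + W, dt)
      sdrop <- max(leaves[[li]]$s, 0)
      drop_mat[k, li] <- sdrop
      xi_mat[k, li] <- rigid_deformation_index(geoms[[li]], sdrop)
    }
    hist_imp[k] <- impacts_cum
    ledger[k, ] <- c(
      sprayed = sum(mass[state != 0L]),
      airborne = sum(mass[state == 1L]),
      deposited = sum(mass[state == 2L]),
      rebounded = sum(mass[state == 3L]),
      splashed = sum(mass[state == 4L]),
      ground = sum(mass[state == 5L]),
      escaped = sum(mass[state == 6L]),
      pending = sum(mass[state == 0L])
    )
  }

  times <- seq_len(nsteps) * dt
  history <- tibble(
    impacts_cum = hist_imp,
    xi_frac = apply(sweep(xi_mat, 2, lv$xi_parallel, "/"), 1, max),
    drop_frac = apply(sweep(drop_mat, 2, lv$tip_threshold, "/"), 1, max)
  )
  stage <- classify_stage(history)
  trace <- tibble(
    time = rep(times, nl),
    leaf = rep(lv$leaf, each = nsteps),
    tip_drop = as.vector(drop_mat),
    xi = as.vector(xi_mat)
  )
  structure(
    list(
      trace = trace,
      stage_timeline = tibble(time = times, stage = stage),
      ledger = as_tibble(cbind(tibble(time = times), as_tibble(ledger))),
      ground_hits = tibble(x = ground_x, y = ground_y, mass = ground_m),
      films = films, leaves_final = leaves,
      n_droplets = n, plant = plant, op = op, config = config,
      droplet = droplet
    ),
    class = "spray_sim"
  )
}

#' @export
print.spray_sim <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<spray_sim> %d droplets over %g s; max xi = %.4f; final stage: %s\n",
    x$n_droplets, x$config$duration, g$max_xi, g$final_stage))
  cat(sprintf("  deposited %.1f%% of sprayed mass; mass balance error %.2e\n",
              100 * g$deposited_frac, g$mass_error))
  invisible(x)
}

#' @describeIn run_simulation Per-leaf deformation trace as a tibble.
#' @param x,object A `spray_sim`.
#' @param ... Unused.
#' @export
tidy.spray_sim <- function(x, ...) {
  dplyr::left_join(x$trace, x$stage_timeline, by = "time")
}

#' @describeIn run_simulation One-row run summary: maximum deformation
#'   index, final stage, deposited mass fraction and the worst relative
#'   mass-ledger error.
#' @export
glance.spray_sim <- function(x, ...) {
  if (nrow(x$ledger) == 0) {
    return(tibble(max_xi = NA_real_, final_stage = NA_character_,
                  deposited_frac = NA_real_, mass_error = NA_real_,
                  n_droplets = x$n_droplets))
  }
  parts <- x$ledger$airborne + x$ledger$deposited + x$ledger$rebounded +
    x$ledger$splashed + x$ledger$ground + x$ledger$escaped
  err <- max(abs(parts - x$ledger$sprayed) / pmax(x$ledger$sprayed, 1e-300))
  last <- x$ledger[nrow(x$ledger), ]
  tibble(
    max_xi = max(x$trace$xi),
    final_stage = as.character(x$stage_timeline$stage[nrow(x$stage_timeline)]),
    deposited_frac = last$deposited / max(last$sprayed, 1e-300),
    mass_error = err,
    n_droplets = x$n_droplets
  )
}

#' @export
autoplot.spray_sim <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$time, y = .data$xi,
             group = .data$leaf, colour = factor(.data$leaf))) +
    geom_line(alpha = 0.8) +
    labs(x = "time (s)", y = "leaf deformation index",
         colour = "leaf", title = "Leaf deformation under spray impact")
}
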