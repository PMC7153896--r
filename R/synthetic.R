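#' Parameters of the synthetic pole-to-pole trajectory generator
#'
#' The generator emulates quasi-periodic pole-to-pole migration with fully
#' known ground truth, so the analysis pipeline can be validated without
#' simulation runs: constant run speed `v_run` in the lane centre, constant
#' deceleration from `ramp_xi` (distance from the tip where the speed
#' taper begins) down to a stop at `turn_point` (closest approach of the
#' centre of mass to the tip), a gamma-distributed stationary pause, and a
#' mirror-image acceleration back out; sampled every `dt` minutes with
#' additive Gaussian position noise.
#'
#' Defaults encode the statistics reported for MDA-MB-231 cells on
#' stripe microlanes: plateau speed 0.62 um/min, speed decline starting
#' 55 um from the tips, and a mean tip-region reversal time near 100 min
#' (ground truth 116.9 min with the default 13-um ramp and 33-min mean
#' pause; the corresponding period-length line has slope 2/v_run and
#' x-intercept 37.5 um).
#'
#' @param lane_length Lane length, micrometres.
#' @param v_run Plateau speed, um/min.
#' @param ramp_xi Distance from each tip where deceleration begins, um.
#' @param turn_point Closest approach of the trace to the tip, um.
#' @param pause_mean Mean stationary pause at the turn point, minutes.
#' @param pause_shape Gamma shape parameter of the pause distribution.
#' @param noise_sd Per-sample Gaussian position noise, um.
#' @param dt Sampling interval, minutes.
#' @param duration Track duration, minutes (default 2160 = 36 h).
#' @param seed Optional seed.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(lane_length = 170, v_run = 0.62, ramp_xi = 55,
                             turn_point = 42, pause_mean = 33,
                             pause_shape = 4, noise_sd = 1, dt = 10,
                             duration = 2160, seed = NULL) {
  stopifnot(turn_point < ramp_xi, ramp_xi < lane_length / 2, v_run > 0,
            pause_mean >= 0, pause_shape > 0, noise_sd >= 0, dt > 0,
            duration >= dt)
  structure(list(lane_length = lane_length, v_run = v_run, ramp_xi = ramp_xi,
                 turn_point = turn_point, pause_mean = pause_mean,
                 pause_shape = pause_shape, noise_sd = noise_sd, dt = dt,
                 duration = duration, seed = seed),
            class = "generator_params")
}

#' Ground-truth kinematic summaries of a generator parameter set
#'
#' Closed-form values implied by the piecewise kinematics: ramp traversal
#' time `2 * (ramp_xi - turn_point) / v_run` (constant deceleration), mean
#' reversal time inside a tip region of width `xi0 >= ramp_xi`, and the
#' mean cycle period.
#'
#' @param params A [generator_params()].
#' @param xi0 Tip-region width for the reversal-time truth, um.
#' @return List with `ramp_traversal`, `mean_t_R`, `mean_cycle_period`
#'   (minutes) and `slope_h_per_um` of the period-length line.
#' @export
generator_truth <- function(params, xi0 = params$ramp_xi) {
  v <- params$v_run
  delta <- params$ramp_xi - params$turn_point
  ramp <- 2 * delta / v
  if (xi0 < params$ramp_xi - 1e-9)
    stop("xi0 smaller than ramp_xi: region reversal time has no closed form")
  t_R <- 2 * (xi0 - params$ramp_xi) / v + 2 * ramp + params$pause_mean
  cyc <- 2 * ((params$lane_length - 2 * params$ramp_xi) / v + 2 * ramp +
                params$pause_mean)
  list(ramp_traversal = ramp, mean_t_R = t_R, mean_cycle_period = cyc,
       slope_h_per_um = 2 / v / 60)
}

#' Pause mean needed for a target mean reversal time
#'
#' Inverts [generator_truth()]: given a tip-region width `xi0` and a target
#' mean region-occupancy (reversal) time, returns the pause mean such that
#' expected approach + ramp traversals + pause equal the target.
#'
#' @param params A [generator_params()].
#' @param target_tR_mean Target mean reversal time, minutes.
#' @param xi0 Tip-region width, um (default `ramp_xi`).
#' @return Pause mean in minutes.
#' @export
pause_for_target_reversal_time <- function(params, target_tR_mean,
                                           xi0 = params$ramp_xi) {
  v <- params$v_run
  delta <- params$ramp_xi - params$turn_point
  travel <- 2 * (xi0 - params$ramp_xi) / v + 4 * delta / v
  if (target_tR_mean < travel - 1e-9)
    stop(sprintf("infeasible target: traversal alone takes %.1f min", travel))
  target_tR_mean - travel
}

# piecewise kinematics: returns data.frame of segments
# type: run / decel / pause / accel; closed-form evaluation per segment
.generate_segments <- function(p) {
  v <- p$v_run
  L <- p$lane_length
  delta <- p$ramp_xi - p$turn_point
  a <- if (delta > 0) v^2 / (2 * delta) else Inf
  td <- if (delta > 0) 2 * delta / v else 0
  xp <- L / 2 - p$ramp_xi       # plateau edge (absolute koor)
  xt <- L / 2 - p$turn_point    # turn point (absolute koor)
  segs <- list()
  t <- 0
  x <- stats::runif(1, -xp, xp)
  dir <- sample(c(-1, 1), 1)
  turn_log <- list()
  while (t < p$duration + p$dt) {
    # run phase to plateau edge
    run_d <- (dir * xp - x) * dir
    if (run_d > 1e-12) {
      segs[[length(segs) + 1]] <- list(type = "run", t0 = t, t1 = t + run_d / v,
                                       x0 = x, v = dir * v)
      t <- t + run_d / v
      x <- dir * xp
    }
    if (td > 0) {
      segs[[length(segs) + 1]] <- list(type = "decel", t0 = t, t1 = t + td,
                                       x0 = x, v = dir * v, a = -dir * a)
      t <- t + td
      x <- dir * xt
    }
    pause <- if (p$pause_mean > 0)
      stats::rgamma(1, shape = p$pause_shape,
                    rate = p$pause_shape / p$pause_mean) else 0
    turn_log[[length(turn_log) + 1]] <-
      data.frame(side = if (dir > 0) "right" else "left",
                 t_arrive = t, t_depart = t + pause, pause = pause)
    if (pause > 0) {
      segs[[length(segs) + 1]] <- list(type = "pause", t0 = t, t1 = t + pause,
                                       x0 = x, v = 0)
      t <- t + pause
    }
    dir <- -dir
    if (td > 0) {
      segs[[length(segs) + 1]] <- list(type = "accel", t0 = t, t1 = t + td,
                                       x0 = x, v = 0, a = dir * a)
      t <- t + td
      x <- x + dir * delta
    }
  }
  list(segments = segs, turns = do.call(rbind, turn_log))
}

.eval_segments <- function(segs, times) {
  x <- numeric(length(times))
  t0s <- vapply(segs, function(s) s$t0, 0)
  for (i in seq_along(times)) {
    k <- findInterval(times[i], t0s)
    s <- segs[[max(k, 1)]]
    dtl <- times[i] - s$t0
    x[i] <- switch(s$type,
                   run = s$x0 + s$v * dtl,
                   pause = s$x0,
                   decel = s$x0 + s$v * dtl + 0.5 * s$a * dtl^2,
                   accel = s$x0 + 0.5 * s$a * dtl^2)
  }
  x
}

#' Generate one synthetic pole-to-pole trajectory
#'
#' @param params A [generator_params()].
#' @param cell_id Label for the track.
#' @return A [lane_trajectory()] with attributes `truth` (list with the
#'   turning log and [generator_truth()] values) and `params`.
#' @export
generate_trajectory <- function(params, cell_id = "synth") {
  stopifnot(inherits(params, "generator_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  gen <- .generate_segments(params)
  times <- seq(0, params$duration, by = params$dt)
  x <- .eval_segments(gen$segments, times)
  if (params$noise_sd > 0) x <- x + stats::rnorm(length(x), 0, params$noise_sd)
  tr <- lane_trajectory(times, x, lane_length = params$lane_length,
                        cell_id = cell_id)
  attr(tr, "truth") <- list(turns = gen$turns,
                            summary = generator_truth(params))
  attr(tr, "params") <- params
  tr
}

#' Generate a synthetic trajectory ensemble across lane lengths
#'
#' Draws one independent seed per track from the master seed (so tracks
#' are invariant under reordering) and builds the manifest expected by the
#' analysis pipeline.
#'
#' @param params A [generator_params()]; its `lane_length` is overridden
#'   per ensemble member.
#' @param n_cells Tracks per lane length.
#' @param lane_lengths Numeric vector of lane lengths, um.
#' @param seed Master seed.
#' @return List with `tracks` (named list of trajectories), `manifest`
#'   (data.frame `id`, `lane_length`, `width`, `tip_shape`, `source`) and
#'   `truth` (turning logs per track).
#' @export
generate_ensemble <- function(params, n_cells = 100,
                              lane_lengths = c(120, 170, 220, 270),
                              seed = 1) {
  stopifnot(n_cells >= 1)
  set.seed(seed)
  total <- n_cells * length(lane_lengths)
  seeds <- sample.int(.Machine$integer.max - 1, total)
  tracks <- vector("list", total)
  ids <- character(total)
  man <- vector("list", total)
  k <- 0
  for (L in lane_lengths) {
    pL <- params
    pL$lane_length <- L
    for (c in seq_len(n_cells)) {
      k <- k + 1
      id <- sprintf("L%g_c%03d", L, c)
      pL$seed <- seeds[k]
      tracks[[k]] <- generate_trajectory(pL, cell_id = id)
      ids[k] <- id
      man[[k]] <- data.frame(id = id, lane_length = L, width = 20,
                             tip_shape = "round", source = "synthetic")
    }
  }
  names(tracks) <- ids
  list(tracks = tracks, manifest = do.call(rbind, man),
       truth = lapply(tracks, function(t) attr(t, "truth")))
}
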