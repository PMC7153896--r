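#' Parameters of the extended Cellular Potts model
#'
#' The model couples a standard area/perimeter Hamiltonian,
#' `H = kappa_A * A^2 + kappa_P * P^2 - sum_x eps(x, t)`,
#' to a per-site polarization field `eps(x, t)` confined to
#' `[eps0 - delta_eps/2, eps0 + delta_eps/2]`. Accepted protrusions
#' (retractions) drive `eps` of surrounding sites towards the upper (lower)
#' bound at rate `mu`; unperturbed sites relax to `eps0`. Large `eps` makes
#' further protrusion cheaper, closing the positive feedback loop that
#' polarizes the cell.
#'
#' Defaults are implementation choices (no published parameter table is
#' reproduced here), tuned so that a cell on a 20-um lane reaches a steady
#' contact area of about 750 um^2 (a polarized length of roughly 45-55 um),
#' migrates persistently, and can be speed-calibrated to experimental
#' values via [calibrate_mcs_duration()].
#'
#' @param kappa_A Area stiffness, energy per um^4.
#' @param kappa_P Perimeter stiffness, energy per um^2.
#' @param eps0 Resting polarization field, energy per site.
#' @param delta_eps Polarization range (full width), energy per site.
#' @param mu Field relaxation rate, per minute.
#' @param signaling_R Signaling radius for the protrusion/retraction
#'   neighbourhood count, micrometres.
#' @param kT Metropolis temperature, energy.
#' @param mcs_minutes Physical duration of one Monte Carlo step, minutes;
#'   usually set by [calibrate_mcs_duration()].
#' @param spacing Lattice spacing, micrometres per site.
#' @return An object of class `model_params`.
#' @export
model_params <- function(kappa_A = 5.5e-4, kappa_P = 5e-4, eps0 = 3.3,
                         delta_eps = 9, mu = 0.2, signaling_R = 5,
                         kT = 0.2, mcs_minutes = 0.23, spacing = 2) {
  p <- list(kappa_A = kappa_A, kappa_P = kappa_P, eps0 = eps0,
            delta_eps = delta_eps, mu = mu, signaling_R = signaling_R,
            kT = kT, mcs_minutes = mcs_minutes, spacing = spacing)
  stopifnot(kappa_A > 0, kappa_P > 0, eps0 > 0, delta_eps >= 0, mu > 0,
            signaling_R > 0, kT > 0, mcs_minutes > 0, spacing > 0)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("extended CPM parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  cat(sprintf("  (steady-state area ~ %.0f um^2)\n", steady_state_area(x)))
  invisible(x)
}

#' Estimated steady-state contact area
#'
#' At equilibrium the marginal area cost of one more site,
#' `kappa_A * (2 A h^2 + h^4)`, balances the polarization gain `eps0`
#' (perimeter-neutral additions), giving `A* ~ eps0 / (2 kappa_A h^2)` in
#' um^2. Used to size the initial cell.
#'
#' @param params A [model_params()].
#' @return Area in um^2.
#' @export
steady_state_area <- function(params) {
  params$eps0 / (2 * params$kappa_A * params$spacing^2)
}

#' Initialize a cell state on a lane mask
#'
#' Places a compact disc of occupied sites at the lane centre with the
#' polarization field at its rest value `eps0` everywhere.
#'
#' @param mask A [make_mask()] result.
#' @param params A [model_params()].
#' @param area Target initial area in um^2 (default: [steady_state_area()]).
#' @return An object of class `cpm_state`: list with logical matrix `occ`,
#'   numeric matrix `eps` (NA outside the cell), integer matrix `label`
#'   (per-MCS event labels: +1 protruded, -1 retracted, 0 unchanged) and
#'   `time` in minutes.
#' @export
init_cell_state <- function(mask, params, area = steady_state_area(params)) {
  stopifnot(inherits(mask, "lane_mask"))
  h <- mask$spacing
  r <- sqrt(area / pi)
  occ <- outer(mask$x, rep(1, length(mask$y)))^2 +
    outer(rep(1, length(mask$x)), mask$y)^2 <= r^2
  occ <- occ & mask$grid
  if (!any(occ)) stop("initial cell empty: mask cannot host the requested area")
  eps <- matrix(NA_real_, nrow(occ), ncol(occ))
  eps[occ] <- params$eps0
  structure(list(occ = occ, eps = eps,
                 label = matrix(0L, nrow(occ), ncol(occ)), time = 0),
            class = "cpm_state")
}

.cpm_eps_filled <- function(state, params) {
  eps <- state$eps
  eps[is.na(eps)] <- params$eps0
  eps
}

#' Configuration energy of a cell state
#'
#' Recomputes `H = kappa_A A^2 + kappa_P P^2 - sum eps` from scratch in R:
#' `A` is the occupied-site count times `spacing^2` (um^2) and `P` the
#' number of exposed 4-neighbour edges times `spacing` (um). This is the
#' reference implementation against which the incremental bookkeeping of
#' the compiled kernel is verified.
#'
#' @param state A `cpm_state`.
#' @param params A [model_params()].
#' @return Energy (scalar).
#' @export
hamiltonian <- function(state, params) {
  occ <- state$occ
  if (!any(occ)) stop("empty cell has no defined energy")
  h <- params$spacing
  nx <- nrow(occ); ny <- ncol(occ)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- occ
  exposed <- 0L
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad[2:(nx + 1) + sh[1], 2:(ny + 1) + sh[2]]
    exposed <- exposed + sum(occ & !nb)
  }
  A <- sum(occ) * h^2
  P <- exposed * h
  params$kappa_A * A^2 + params$kappa_P * P^2 - sum(state$eps[occ])
}

.params_list <- function(params) {
  list(kappa_A = params$kappa_A, kappa_P = params$kappa_P, eps0 = params$eps0,
       delta_eps = params$delta_eps, mu = params$mu,
       signaling_R = params$signaling_R, kT = params$kT,
       mcs_minutes = params$mcs_minutes, spacing = params$spacing)
}

#' Attempt one elementary Metropolis move
#'
#' Picks a random occupied site and one of its 4-neighbours, then attempts
#' either a protrusion into an empty neighbour or a retraction of the
#' picked boundary site (with equal probability). The move is accepted with
#' probability `min(1, exp(-dH/kT))`; protrusions outside the adhesive mask
#' are never accepted, and retractions that would disconnect or empty the
#' cell are rejected. A newly protruded site copies the polarization value
#' of the occupied site that sourced the protrusion.
#'
#' @param state A `cpm_state`.
#' @param mask A `lane_mask`.
#' @param params A [model_params()].
#' @return List with the updated `state` and fields `accepted`,
#'   `evaluated`, `type` (+1 protrusion, -1 retraction, 0 no candidate),
#'   `site` (row/col indices or NA) and `dH`.
#' @export
attempt_step <- function(state, mask, params) {
  res <- cpp_single_attempt(mask$grid, state$occ, .cpm_eps_filled(state, params),
                            .params_list(params))
  new_label <- state$label
  new_label[res$label != 0L] <- res$label[res$label != 0L]
  eps <- res$eps
  st <- structure(list(occ = res$occ, eps = eps, label = new_label,
                       time = state$time), class = "cpm_state")
  list(state = st, accepted = res$accepted, evaluated = res$evaluated,
       type = res$type, site = c(res$i, res$j), dH = res$dH)
}

#' Classify site neighbourhoods by local event balance
#'
#' For each occupied site, counts accepted protrusion and retraction events
#' (from the state's per-MCS labels) within Euclidean distance
#' `signaling_R` and classifies the site as protrusive (+1, more
#' protrusions), retracting (-1, more retractions) or neutral (0, ties or
#' no events).
#'
#' @param state A `cpm_state` whose `label` matrix holds one MCS of events.
#' @param params A [model_params()].
#' @return Integer matrix of classes (NA outside the cell).
#' @export
classify_neighborhoods <- function(state, params) {
  h <- params$spacing; R <- params$signaling_R
  lab <- state$label
  ev <- which(lab != 0L, arr.ind = TRUE)
  cls <- matrix(NA_integer_, nrow(lab), ncol(lab))
  occ_idx <- which(state$occ, arr.ind = TRUE)
  if (nrow(occ_idx) == 0) return(cls)
  p <- integer(nrow(occ_idx)); r <- integer(nrow(occ_idx))
  if (nrow(ev) > 0) {
    for (k in seq_len(nrow(ev))) {
      d2 <- ((occ_idx[, 1] - ev[k, 1])^2 + (occ_idx[, 2] - ev[k, 2])^2) * h^2
      within <- d2 <= R^2 + 1e-12
      if (lab[ev[k, 1], ev[k, 2]] > 0L) p <- p + within else r <- r + within
    }
  }
  cls[occ_idx] <- as.integer(sign(p - r))
  cls
}

#' Relax the polarization field for one time step
#'
#' Applies the exact exponential update
#' `eps <- target + (eps - target) * exp(-mu * dt)` per occupied site, with
#' target `eps0 + delta_eps/2` for protrusive sites, `eps0 - delta_eps/2`
#' for retracting sites and `eps0` for neutral sites; the bounds
#' `[eps0 - delta_eps/2, eps0 + delta_eps/2]` are preserved.
#'
#' @param state A `cpm_state`.
#' @param classes Integer matrix from [classify_neighborhoods()].
#' @param params A [model_params()].
#' @param dt Time step in minutes (normally `mcs_minutes`).
#' @return The updated `cpm_state`.
#' @export
update_polarization <- function(state, classes, params, dt = params$mcs_minutes) {
  f <- exp(-params$mu * dt)
  lo <- params$eps0 - params$delta_eps / 2
  hi <- params$eps0 + params$delta_eps / 2
  tgt <- matrix(params$eps0, nrow(state$eps), ncol(state$eps))
  tgt[!is.na(classes) & classes > 0L] <- hi
  tgt[!is.na(classes) & classes < 0L] <- lo
  eps <- tgt + (state$eps - tgt) * f
  eps <- pmin(pmax(eps, lo), hi)
  eps[!state$occ] <- NA_real_
  state$eps <- eps
  state$time <- state$time + dt
  state
}

#' Simulate a single cell on a microlane
#'
#' Runs the extended Cellular Potts model: per Monte Carlo step (MCS), one
#' attempted elementary move per boundary site on average, followed by
#' neighbourhood classification and polarization relaxation with
#' `dt = mcs_minutes`. The cell starts as a compact disc at the lane centre
#' with `eps = eps0`; a burn-in window is discarded before recording. The
#' centre-of-mass koor coordinate is sampled every `sampling` minutes.
#' Identical seeds give bit-identical records.
#'
#' @param mask A [make_mask()] result.
#' @param params A [model_params()].
#' @param duration Recorded duration in minutes (default 2160 = 36 h).
#' @param sampling Sampling interval in minutes (default 10, mirroring
#'   time-lapse experiments).
#' @param burn_in Discarded initial window in minutes.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param record_fields Record per-sample polarization-field snapshots
#'   (array `nx x ny x n_samples`), e.g. for kymographs.
#' @param record_shapes Record per-sample occupancy masks.
#' @param init_area Initial cell area in um^2.
#' @param check_bounds Assert the polarization bounds every MCS (debug).
#' @return An object of class `lane_sim`: list with `trajectory`
#'   (data.frame `time`, `koor`), per-sample `area`, `perimeter`,
#'   `width_lead`, `width_trail`, the final `state`, `acceptance_rate`,
#'   optional `field_series`/`shape_series`, `params`, `mask` and `seed`.
#' @export
run_simulation <- function(mask, params, duration = 2160, sampling = 10,
                           burn_in = 240, seed = NULL, record_fields = FALSE,
                           record_shapes = FALSE,
                           init_area = steady_state_area(params),
                           check_bounds = FALSE) {
  stopifnot(inherits(mask, "lane_mask"), inherits(params, "model_params"),
            duration >= sampling)
  if (!is.null(seed)) set.seed(seed)
  st <- init_cell_state(mask, params, init_area)
  res <- cpp_run_simulation(mask$grid, st$occ, .cpm_eps_filled(st, params),
                            .params_list(params), duration, sampling, burn_in,
                            record_fields, record_shapes, check_bounds)
  traj <- lane_trajectory(res$time, res$koor,
                          lane_length = mask$spec$length_L,
                          cell_id = "sim")
  out <- list(trajectory = traj, area = res$area, perimeter = res$perimeter,
              width_lead = res$width_lead, width_trail = res$width_trail,
              state = structure(list(occ = res$occ, eps = res$eps,
                                     label = matrix(0L, nrow(res$occ), ncol(res$occ)),
                                     time = duration), class = "cpm_state"),
              acceptance_rate = res$acceptance_rate,
              params = params, mask = mask, seed = seed)
  if (record_fields) out$field_series <- res$field_series
  if (record_shapes) out$shape_series <- res$shape_series
  structure(out, class = "lane_sim")
}

#' @export
print.lane_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("lane_sim: %d samples over %g min; mean area %.0f um^2; acceptance %.2f\n",
              nrow(tr), max(tr$time), mean(x$area), x$acceptance_rate))
  invisible(x)
}

#' Calibrate the physical duration of a Monte Carlo step
#'
#' Measures the mean absolute centre-of-mass velocity of the migrating cell
#' in the lane's plateau region (|koor| < L/2 - xi0) and rescales
#' `mcs_minutes` so that this speed matches `target_speed`. The model's
#' kinetics are defined per Monte Carlo step, so calibration is a pure
#' relabelling of time: `mu` is co-rescaled to keep the per-MCS relaxation
#' factor `mu * mcs_minutes` unchanged. The measurement is repeated to
#' average out run-to-run variability.
#'
#' @param mask A [make_mask()] result.
#' @param params A [model_params()] with `delta_eps > 0` (the unpolarized
#'   model does not migrate and cannot be calibrated).
#' @param target_speed Desired plateau mean absolute speed, um/min
#'   (default 0.6, the experimental value).
#' @param duration Measurement duration per run, minutes.
#' @param n_cells Independent measurement runs averaged per pass.
#' @param xi0 Tip region excluded from the plateau, micrometres.
#' @param iterations Measure-and-rescale passes.
#' @param seed Optional seed for the measurement runs.
#' @param sampling Sampling interval for the measurement, minutes.
#' @return A `model_params` with calibrated `mcs_minutes`; the last
#'   measured plateau speed is attached as attribute `measured_speed`.
#' @export
calibrate_mcs_duration <- function(mask, params, target_speed = 0.6,
                                   duration = 2880, n_cells = 3, xi0 = 55,
                                   iterations = 2, seed = NULL,
                                   sampling = 10) {
  stopifnot(target_speed > 0)
  if (params$delta_eps <= 0)
    stop("delta_eps = 0: no polarization feedback, cell does not migrate")
  if (!is.null(seed)) set.seed(seed)
  L <- mask$spec$length_L
  v_meas <- NA_real_
  for (it in seq_len(iterations)) {
    vs <- vapply(seq_len(n_cells), function(run) {
      sim <- run_simulation(mask, params, duration = duration,
                            sampling = sampling, burn_in = 240)
      tr <- sim$trajectory
      v <- diff(tr$koor) / diff(tr$time)
      plateau <- abs(tr$koor[-nrow(tr)]) < L / 2 - xi0 &
        abs(tr$koor[-1]) < L / 2 - xi0
      if (sum(plateau) < 10)
        stop("too few plateau samples: lane too short for calibration at this xi0")
      mean(abs(v[plateau]))
    }, 0)
    v_meas <- mean(vs)
    if (v_meas < 0.02)
      stop("cell is not migrating persistently; cannot calibrate speed")
    # speed in um/MCS is v_meas * mcs_minutes; solve for the new duration,
    # rescaling mu so the dynamics are unchanged in MCS units
    mcs_new <- v_meas * params$mcs_minutes / target_speed
    params$mu <- params$mu * params$mcs_minutes / mcs_new
    params$mcs_minutes <- mcs_new
  }
  attr(params, "measured_speed") <- v_meas
  params
}
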