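#' Construct a 1D microlane trajectory
#'
#' A trajectory is a uniformly sampled time series of the cell's long-axis
#' coordinate ("koor"): micrometres from the lane centre, sampled in
#' minutes (10-min intervals in the experiments this package mirrors).
#'
#' @param time Times in minutes, uniformly spaced.
#' @param koor Long-axis coordinates in micrometres from the lane centre.
#' @param lane_length Lane length in micrometres.
#' @param cell_id Label for the cell.
#' @return A data.frame of class `lane_trajectory` with columns `time`,
#'   `koor` and attributes `lane_length`, `cell_id`, `dt`.
#' @export
lane_trajectory <- function(time, koor, lane_length = NA_real_,
                            cell_id = "cell") {
  stopifnot(length(time) == length(koor), length(time) >= 2)
  dts <- diff(time)
  if (any(dts <= 0)) stop("time must be strictly increasing")
  if (max(dts) - min(dts) > 1e-6 * max(dts))
    stop("non-uniform sampling interval")
  structure(data.frame(time = time, koor = koor),
            lane_length = lane_length, cell_id = cell_id, dt = dts[1],
            class = c("lane_trajectory", "data.frame"))
}

.traj_dt <- function(traj) {
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- diff(traj$time[1:2])
  dt
}

.traj_L <- function(traj, lane_length = NULL) {
  if (!is.null(lane_length)) return(lane_length)
  L <- attr(traj, "lane_length")
  if (is.null(L) || is.na(L)) stop("lane_length unknown for this trajectory")
  L
}

#' Project a raw 2D track onto the lane axis and centre it
#'
#' Keeps only the long-axis component of the positions. The lane centre of
#' each track is estimated as the midpoint between the two extreme
#' positions (the closest approaches to either tip), following the
#' convention used for nucleus tracks on microlanes; `koor` is reported
#' relative to that centre. Tracks that never approach both tips (range
#' below half the lane length) fall back to the geometric mask centre and
#' are flagged.
#'
#' @param raw A data.frame with columns `time` and `x` (long-axis position
#'   in an arbitrary frame, micrometres), optionally `y`.
#' @param lane_length Lane length in micrometres (enables the fallback
#'   check); optional.
#' @param mask_centre Long-axis coordinate of the mask centre in the raw
#'   frame, used as fallback (default 0).
#' @param cell_id Label.
#' @return A [lane_trajectory()] with attribute `centered_by` equal to
#'   `"extremes"` or `"mask_centre"` (fallback, with a warning).
#' @export
project_and_center <- function(raw, lane_length = NA_real_, mask_centre = 0,
                               cell_id = "cell") {
  stopifnot(all(c("time", "x") %in% names(raw)))
  x <- raw$x
  rng <- range(x)
  centered_by <- "extremes"
  centre <- mean(rng)
  if (diff(rng) < 1e-9) {
    warning("track has no long-axis motion; flagged degenerate")
    centered_by <- "degenerate"
    centre <- mask_centre
  } else if (!is.na(lane_length) && diff(rng) < lane_length / 2) {
    warning("track never approaches both tips; centring on the mask centre")
    centered_by <- "mask_centre"
    centre <- mask_centre
  }
  tr <- lane_trajectory(raw$time, x - centre, lane_length, cell_id)
  attr(tr, "centered_by") <- centered_by
  tr
}

#' Instantaneous velocities by forward difference
#'
#' `v(t) = [x(t + dt) - x(t)] / dt` with the trajectory's own uniform
#' sampling interval (10 min in the experiments).
#'
#' @param traj A [lane_trajectory()].
#' @return A data.frame with columns `time` (interval start) and `v`
#'   (um/min); one row fewer than the trajectory.
#' @export
instantaneous_velocity <- function(traj) {
  dts <- diff(traj$time)
  if (max(dts) - min(dts) > 1e-6 * max(dts))
    stop("non-uniform timestamps")
  data.frame(time = traj$time[-length(traj$time)], v = diff(traj$koor) / dts)
}

#' Filter a track ensemble by the standard exclusion rules
#'
#' Retains tracks that (i) last at least `min_duration` minutes, (ii)
#' explore the whole stripe, i.e. reach both tip regions (within `xi0` of
#' either tip), and (iii) show net motion (mean absolute velocity at least
#' `min_mean_speed`). An exclusion report counts tracks per reason (the
#' first failing rule is reported).
#'
#' @param tracks Named list of [lane_trajectory()] objects.
#' @param lane_length Lane length in micrometres (defaults to each track's
#'   own attribute).
#' @param min_duration Minimum duration, minutes (default 2160 = 36 h).
#' @param xi0 Tip-region width used for the "explored the whole stripe"
#'   rule, micrometres.
#' @param min_mean_speed Minimum mean |v| in um/min.
#' @return List with `tracks` (retained), `report` (data.frame of reason
#'   counts) and `excluded` (named character vector of reasons).
#' @export
filter_tracks <- function(tracks, lane_length = NULL, min_duration = 2160,
                          xi0 = 55, min_mean_speed = 0.05) {
  stopifnot(is.list(tracks), length(tracks) > 0)
  reasons <- character(0)
  keep <- logical(length(tracks))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    L <- .traj_L(tr, lane_length)
    dur <- max(tr$time) - min(tr$time)
    v <- diff(tr$koor) / diff(tr$time)
    reason <- NA_character_
    if (dur < min_duration - 1e-9) {
      reason <- "short"
    } else if (!(max(tr$koor) > L / 2 - xi0 && min(tr$koor) < -(L / 2 - xi0))) {
      reason <- "did_not_explore_whole_stripe"
    } else if (mean(abs(v)) < min_mean_speed) {
      reason <- "non_moving"
    }
    keep[k] <- is.na(reason)
    if (!is.na(reason)) {
      nm <- attr(tr, "cell_id"); if (is.null(nm)) nm <- as.character(k)
      reasons[nm] <- reason
    }
  }
  if (!any(keep))
    stop("no tracks retained: check lane metadata and filter rules")
  tab <- table(factor(reasons, levels = c("short",
                                          "did_not_explore_whole_stripe",
                                          "non_moving")))
  list(tracks = tracks[keep],
       report = data.frame(reason = names(tab), excluded = as.integer(tab)),
       excluded = reasons)
}

#' Spatial occupancy and mean-speed profiles
#'
#' Bins cell positions into `bin_width`-wide sections along the lane
#' (5-um bins by default) and reports the occupancy fraction `p(x)` and the
#' mean absolute velocity per bin with its standard error. Each velocity is
#' assigned to the bin of its interval's start position. Empty bins carry
#' `NA` (never zero).
#'
#' @param tracks A [lane_trajectory()] or list of them (common lane length).
#' @param lane_length Lane length in micrometres.
#' @param bin_width Bin width in micrometres (default 5).
#' @return A data.frame of class `spatial_profile` with columns
#'   `bin_center`, `p`, `mean_abs_v`, `sem`, `n_pos`, `n_v` and attributes
#'   `lane_length`, `bin_width`.
#' @export
spatial_profiles <- function(tracks, lane_length = NULL, bin_width = 5) {
  if (inherits(tracks, "lane_trajectory")) tracks <- list(tracks)
  L <- .traj_L(tracks[[1]], lane_length)
  nbin <- ceiling(L / bin_width)
  breaks <- seq(-nbin * bin_width / 2, nbin * bin_width / 2, by = bin_width)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  pos <- unlist(lapply(tracks, function(t) t$koor))
  vstart <- unlist(lapply(tracks, function(t) t$koor[-nrow(t)]))
  vabs <- unlist(lapply(tracks, function(t) abs(diff(t$koor) / diff(t$time))))
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks,
                                               rightmost.closed = TRUE), 1L),
                             nbin)
  bp <- bin_of(pos); bv <- bin_of(vstart)
  n_pos <- tabulate(bp, nbin)
  n_v <- tabulate(bv, nbin)
  sum_v <- vapply(seq_len(nbin), function(b) sum(vabs[bv == b]), 0)
  sum_v2 <- vapply(seq_len(nbin), function(b) sum(vabs[bv == b]^2), 0)
  mean_v <- ifelse(n_v > 0, sum_v / n_v, NA_real_)
  sdv <- ifelse(n_v >= 2, sqrt(pmax(sum_v2 / n_v - mean_v^2, 0) * n_v / (n_v - 1)),
                NA_real_)
  sem <- ifelse(n_v >= 2, sdv / sqrt(n_v), NA_real_)
  structure(data.frame(bin_center = centers, p = n_pos / sum(n_pos),
                       mean_abs_v = mean_v, sem = sem,
                       n_pos = n_pos, n_v = n_v),
            lane_length = L, bin_width = bin_width,
            class = c("spatial_profile", "data.frame"))
}

#' Change-point fit of the ramp-plateau-ramp speed profile
#'
#' Fits a continuous trapezoid to the spatial mean-speed profile: two
#' linear ramps at the tips, constrained to start from the profile's
#' outermost observed values, connected by a constant plateau. All
#' breakpoint pairs on the bin grid are searched exhaustively (profiles
#' have at most a few dozen bins, so the least-squares search is exact);
#' for each pair, the plateau level has a closed-form least-squares
#' solution. Ties are broken towards smaller tip-to-breakpoint distances.
#' The tip-to-changepoint distance `xi0` is reported per tip, measured from
#' the lane tip at `+/- L/2`.
#'
#' @param profile A [spatial_profiles()] result.
#' @param lane_length Lane length (defaults to the profile attribute).
#' @return List of class `changepoint_fit`: `xi0_left`, `xi0_right`,
#'   `plateau_speed`, `sse`, `breakpoints` (koor of both change points),
#'   `fully_ramped` flag.
#' @export
fit_changepoints <- function(profile, lane_length = NULL) {
  L <- if (!is.null(lane_length)) lane_length else attr(profile, "lane_length")
  ok <- !is.na(profile$mean_abs_v)
  x <- profile$bin_center[ok]
  y <- profile$mean_abs_v[ok]
  n <- length(x)
  if (n < 6) stop("need at least 6 non-empty bins for a change-point fit")
  vL <- y[1]; vR <- y[n]
  best <- NULL
  for (bl in 1:(n - 1)) {
    for (br in n:(bl + 1)) {
      # design: pred_i = a_i + b_i * m, m the plateau level
      a <- numeric(n); b <- numeric(n)
      if (bl > 1) {
        t_l <- (x[1:bl] - x[1]) / (x[bl] - x[1])
        a[1:bl] <- vL * (1 - t_l); b[1:bl] <- t_l
      } else b[1] <- 1
      if (br < n) {
        t_r <- (x[n] - x[br:n]) / (x[n] - x[br])
        a[br:n] <- vR * (1 - t_r); b[br:n] <- t_r
      } else b[n] <- 1
      mid <- setdiff(seq_len(n), c(1:bl, br:n))
      b[mid] <- 1
      m <- sum((y - a) * b) / sum(b^2)
      sse <- sum((a + b * m - y)^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(bl = bl, br = br, m = m, sse = sse)
      }
    }
  }
  structure(list(
    xi0_left = x[best$bl] + L / 2,
    xi0_right = L / 2 - x[best$br],
    plateau_speed = best$m,
    sse = best$sse,
    breakpoints = c(x[best$bl], x[best$br]),
    fully_ramped = (best$br - best$bl) <= 1
  ), class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf("change-point fit: xi0 = %.1f / %.1f um (left/right), plateau %.3f um/min%s\n",
              x$xi0_left, x$xi0_right, x$plateau_speed,
              if (x$fully_ramped) " [fully ramped]" else ""))
  invisible(x)
}

#' Normalized distribution of absolute velocities
#'
#' Pools |v| over the ensemble and returns a density-normalized histogram
#' (the density integrates to one over the binned range).
#'
#' @param tracks A [lane_trajectory()] or list of them.
#' @param bin_width Histogram bin width in um/min.
#' @return Data.frame with `mid`, `density`, `count`.
#' @export
speed_distribution <- function(tracks, bin_width = 0.05) {
  if (inherits(tracks, "lane_trajectory")) tracks <- list(tracks)
  vabs <- unlist(lapply(tracks, function(t) abs(diff(t$koor) / diff(t$time))))
  stopifnot(length(vabs) > 0)
  top <- max(vabs, bin_width)
  breaks <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  hh <- graphics::hist(vabs, breaks = breaks, plot = FALSE)
  data.frame(mid = hh$mids, density = hh$density, count = hh$counts)
}

#' Ensemble velocity spectrum with log-normal peak fit
#'
#' Computes the magnitude of the discrete Fourier transform of each cell's
#' signed (directional) velocity series after mean removal, truncating all
#' cells to the shortest common length, and averages the spectra over the
#' ensemble (zero-frequency bin excluded). A scaled log-normal curve
#' `a * dlnorm(f, meanlog, sdlog)` is fitted by nonlinear least squares;
#' the dominant frequency `f_max` is the mode of the fitted curve and the
#' migration period is `T = 1/f_max`. If the fit does not converge the raw
#' spectral argmax is used and the result is flagged.
#'
#' @param tracks A [lane_trajectory()] or list of them (common dt).
#' @return List of class `spectral_fit`: `frequencies` (per minute),
#'   `mean_amplitude`, `f_max` (per minute), `meanlog`, `sdlog`,
#'   `period_T` (hours), `fitted` (logical), `n_cells`.
#' @export
velocity_spectrum <- function(tracks) {
  if (inherits(tracks, "lane_trajectory")) tracks <- list(tracks)
  dt <- .traj_dt(tracks[[1]])
  nmin <- min(vapply(tracks, nrow, 0L))
  m <- nmin - 1                       # velocity samples per cell
  if (m < 8) stop("trajectories too short for spectral analysis")
  amp <- matrix(0, length(tracks), floor(m / 2))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    v <- diff(tr$koor[seq_len(nmin)]) / dt
    v <- v - mean(v)
    sp <- Mod(stats::fft(v))
    amp[k, ] <- sp[2:(floor(m / 2) + 1)]
  }
  f <- (seq_len(floor(m / 2))) / (m * dt)
  mean_amp <- colMeans(amp)
  fit <- NULL
  w <- pmax(mean_amp - min(mean_amp), 0)
  if (sum(w) > 0) {
    mlog0 <- sum(w * log(f)) / sum(w)
    slog0 <- sqrt(max(sum(w * (log(f) - mlog0)^2) / sum(w), 1e-4))
    a0 <- max(mean_amp) / stats::dlnorm(exp(mlog0 - slog0^2), mlog0, slog0)
    fit <- tryCatch(
      minpack.lm::nlsLM(mean_amp ~ a * stats::dlnorm(f, meanlog, sdlog),
                        start = list(a = a0, meanlog = mlog0, sdlog = slog0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    f_max <- exp(cf[["meanlog"]] - cf[["sdlog"]]^2)
    if (f_max < f[1] || f_max > f[length(f)]) {
      fit <- NULL                      # fitted peak outside resolved band
    }
  }
  if (is.null(fit)) {
    f_max <- f[which.max(mean_amp)]
    out <- list(frequencies = f, mean_amplitude = mean_amp, f_max = f_max,
                meanlog = NA_real_, sdlog = NA_real_,
                period_T = 1 / f_max / 60, fitted = FALSE,
                n_cells = length(tracks))
  } else {
    cf <- stats::coef(fit)
    out <- list(frequencies = f, mean_amplitude = mean_amp, f_max = f_max,
                meanlog = cf[["meanlog"]], sdlog = cf[["sdlog"]],
                period_T = 1 / f_max / 60, fitted = TRUE,
                n_cells = length(tracks))
  }
  structure(out, class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("spectral fit (%d cells): f_max = %.4g /min, T = %.2f h%s\n",
              x$n_cells, x$f_max, x$period_T,
              if (!x$fitted) " [log-normal fit failed; raw argmax]" else ""))
  invisible(x)
}

#' Migration period versus lane length
#'
#' Ordinary least squares of the migration period `T` (hours) on lane
#' length `L` (micrometres). A cell shuttling at constant speed `v_c` with
#' a length-independent reversal time satisfies `T = (2/v_c) * L + const`,
#' so the crawling speed is `v_c = 2/slope` and the x-intercept bounds the
#' lane length below which no oscillation fits.
#'
#' @param periods Data.frame with columns `lane_length` (um) and
#'   `period` (hours); at least three lengths.
#' @return List of class `period_length_fit`: `slope` (h/um), `slope_se`,
#'   `x_intercept` (um), `v_c` (um/min), `fit` (the `lm` object),
#'   `periods`.
#' @export
period_vs_length <- function(periods) {
  stopifnot(is.data.frame(periods),
            all(c("lane_length", "period") %in% names(periods)))
  if (nrow(periods) < 3) stop("need at least 3 lane lengths")
  fit <- stats::lm(period ~ lane_length, data = periods)
  cf <- stats::coef(fit)
  slope <- cf[["lane_length"]]
  if (slope <= 0) warning("non-positive slope: period does not grow with length")
  # vcov warns on residual-free fits (exact input lines); the se is then 0
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[["lane_length"]])
  structure(list(slope = slope, slope_se = se,
                 x_intercept = -cf[[1]] / slope,
                 v_c = 2 / slope / 60,
                 fit = fit, periods = periods),
            class = "period_length_fit")
}

#' @export
print.period_length_fit <- function(x, ...) {
  cat(sprintf("period vs length: dT/dL = %.4f +/- %.4f h/um, x-intercept %.1f um, v_c = %.3f um/min\n",
              x$slope, x$slope_se, x$x_intercept, x$v_c))
  invisible(x)
}

#' Detect reversal events at the lane tips
#'
#' A reversal event is a maximal interval during which the trajectory lies
#' inside one tip interval of the reversal region: entry time `t1` is the
#' first sample inside, exit time `t2` the first sample after leaving, and
#' the reversal time is `t_R = t2 - t1`. Intervals open at either record
#' end are censored and discarded. The `reversed` flag marks events whose
#' exit moves towards the lane centre after the cell approached the tip.
#'
#' @param traj A [lane_trajectory()].
#' @param region A [reversal_region()] in the same koor frame.
#' @return Data.frame with columns `tip` ("left"/"right"), `t1`, `t2`,
#'   `t_R` (minutes) and `reversed`.
#' @export
detect_reversals <- function(traj, region) {
  stopifnot(inherits(region, "reversal_region"))
  L <- region$lane_length; xi0 <- region$xi0
  out <- list()
  for (side in c("left", "right")) {
    inside <- if (side == "right") traj$koor > L / 2 - xi0
              else traj$koor < -(L / 2 - xi0)
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      if (s == 1 || e == nrow(traj)) next     # censored at a record end
      t1 <- traj$time[s]
      t2 <- traj$time[e + 1]
      deepest <- max(abs(traj$koor[s:e]))
      reversed <- deepest > abs(traj$koor[s]) - 1e-9 &&
        abs(traj$koor[e + 1]) < abs(traj$koor[e])
      out[[length(out) + 1]] <- data.frame(tip = side, t1 = t1, t2 = t2,
                                           t_R = t2 - t1, reversed = reversed)
    }
  }
  if (length(out) == 0)
    return(data.frame(tip = character(0), t1 = numeric(0), t2 = numeric(0),
                      t_R = numeric(0), reversed = logical(0)))
  do.call(rbind, out)
}

#' Mode of a reversal-time histogram
#'
#' Bins reversal times into fixed-width bins starting at zero and returns
#' the midpoint of the most populated bin (first such bin on ties).
#'
#' @param t_R Reversal times in minutes.
#' @param bin_width Bin width in minutes (default 20).
#' @return Bin midpoint in minutes.
#' @export
reversal_time_mode <- function(t_R, bin_width = 20) {
  stopifnot(length(t_R) > 0)
  breaks <- seq(0, ceiling(max(t_R) / bin_width + 1e-9) * bin_width,
                by = bin_width)
  cnt <- graphics::hist(t_R, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mids[which.max(cnt)]
}

#' Kymograph of a simulated run
#'
#' Collapses the per-frame polarization field (or occupancy) over the
#' lane's short axis by taking the maximum at each long-axis position,
#' giving a position-by-time matrix in which a migrating cell appears as a
#' sloped band and pole-to-pole migration as a zigzag.
#'
#' @param sim A [run_simulation()] result with `record_fields = TRUE` (or
#'   `record_shapes = TRUE` for an occupancy kymograph), or a numeric array
#'   `nx x ny x n_frames`.
#' @param what `"eps"` or `"occupancy"`.
#' @return A matrix of class `kymograph` (rows = long-axis positions,
#'   columns = frames) with attributes `x` (koor of rows) and `time`.
#' @export
kymograph <- function(sim, what = c("eps", "occupancy")) {
  what <- match.arg(what)
  if (is.array(sim) && length(dim(sim)) == 3) {
    arr <- sim
    x <- NULL; tm <- seq_len(dim(arr)[3])
  } else {
    stopifnot(inherits(sim, "lane_sim"))
    if (what == "eps") {
      if (is.null(sim$field_series))
        stop("simulation was run without record_fields = TRUE")
      arr <- sim$field_series
    } else {
      if (is.null(sim$shape_series))
        stop("simulation was run without record_shapes = TRUE")
      arr <- vapply(sim$shape_series, function(m) m * 1.0,
                    matrix(0, nrow(sim$state$occ), ncol(sim$state$occ)))
    }
    x <- sim$mask$x; tm <- sim$trajectory$time
  }
  km <- apply(arr, c(1, 3), function(col) {
    if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE)
  })
  structure(km, x = x, time = tm, class = c("kymograph", "matrix"))
}

#' Render a kymograph to a grayscale PNG
#'
#' Rows map to long-axis position and columns to time; intensities are
#' rescaled to [0, 1] with missing values drawn black. A sidecar text file
#' records the axis calibration.
#'
#' @param km A [kymograph()] result.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
write_kymograph_png <- function(km, path) {
  m <- unclass(km)
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) <= 0) rng <- rng + c(0, 1)
  img <- (m - rng[1]) / diff(rng)
  img[is.na(img)] <- 0
  png::writePNG(img, target = path)
  tm <- attr(km, "time")
  writeLines(c(sprintf("rows: long-axis position (%d)", nrow(m)),
               sprintf("cols: time frames (%d), %g..%g min",
                       ncol(m), min(tm), max(tm))),
             paste0(path, ".txt"))
  invisible(path)
}
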