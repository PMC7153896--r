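test_that("projection centres tracks between the extreme approaches", {
  raw <- data.frame(time = seq(0, 100, 10),
                    x = c(80, 60, 30, 0, -40, -78, -50, -20, 10, 50, 79))
  tr <- project_and_center(raw, lane_length = 170)
  expect_equal(max(tr$koor), 79)
  expect_equal(min(tr$koor), -79)
  expect_identical(attr(tr, "centered_by"), "extremes")
  # already-centred symmetric input is unchanged
  raw2 <- data.frame(time = seq(0, 40, 10), x = c(-60, -30, 0, 30, 60))
  expect_equal(project_and_center(raw2, lane_length = 140)$koor, raw2$x)
  # track that never approaches the tips falls back to the mask centre
  raw3 <- data.frame(time = seq(0, 40, 10), x = c(-5, 0, 5, 3, -2))
  expect_warning(tr3 <- project_and_center(raw3, lane_length = 170,
                                           mask_centre = 0), "never approaches")
  expect_identical(attr(tr3, "centered_by"), "mask_centre")
  # purely transverse (constant x) input is flagged degenerate
  raw4 <- data.frame(time = seq(0, 40, 10), x = rep(2, 5))
  expect_warning(tr4 <- project_and_center(raw4), "no long-axis motion")
  expect_identical(attr(tr4, "centered_by"), "degenerate")
})

test_that("velocities are forward differences in um/min", {
  tr <- lane_trajectory(c(0, 10), c(0, 6))
  expect_equal(instantaneous_velocity(tr)$v, 0.6)
  tr2 <- lane_trajectory(seq(0, 50, 10), rep(3, 6))
  expect_true(all(instantaneous_velocity(tr2)$v == 0))
  tr3 <- lane_trajectory(seq(0, 50, 10), 0.25 * seq(0, 50, 10))
  expect_equal(instantaneous_velocity(tr3)$v, rep(0.25, 5))
  expect_error(lane_trajectory(c(0, 10, 30), c(0, 1, 2)), "non-uniform")
})

test_that("track filtering applies the duration, exploration and motion rules", {
  mk <- function(dur, amp, id) {
    t <- seq(0, dur, 10)
    lane_trajectory(t, amp * sin(2 * pi * t / 900), lane_length = 170,
                    cell_id = id)
  }
  tracks <- list(good = mk(2160, 80, "good"),
                 short = mk(1800, 80, "short"),
                 half = mk(2160, 25, "half"))
  flt <- filter_tracks(tracks, xi0 = 55)
  expect_identical(names(flt$tracks), "good")
  expect_identical(unname(flt$excluded["short"]), "short")
  expect_identical(unname(flt$excluded["half"]), "did_not_explore_whole_stripe")
  expect_identical(sum(flt$report$excluded), 2L)
  # an all-passing ensemble has zero exclusions
  flt2 <- filter_tracks(list(a = mk(2160, 80, "a"), b = mk(2160, 80, "b")),
                        xi0 = 55)
  expect_identical(length(flt2$excluded), 0L)
  expect_error(filter_tracks(list(x = mk(600, 80, "x"))), "no tracks")
})

test_that("occupancy is normalized and constant-speed crossings give flat profiles", {
  t <- seq(0, 2160, 10)
  tr <- lane_trajectory(t, -80 + (160 / 2160) * t, lane_length = 170)
  prof <- spatial_profiles(tr, lane_length = 170)
  expect_equal(sum(prof$p), 1, tolerance = 1e-9)
  inner <- prof$mean_abs_v[!is.na(prof$mean_abs_v)]
  expect_true(all(abs(inner - 160 / 2160) < 1e-9))
  # empty bins are NA, not zero
  expect_true(anyNA(prof$mean_abs_v) || all(prof$n_v > 0))
})

test_that("change-point fit recovers ramp boundaries on trapezoids", {
  prof <- trapezoid_profile(L = 270, xi0 = 55, plateau = 0.6)
  fit <- fit_changepoints(prof)
  expect_lte(abs(fit$xi0_left - 55), 5)
  expect_lte(abs(fit$xi0_right - 55), 5)
  expect_equal(fit$plateau_speed, 0.6, tolerance = 0.02)
  expect_false(fit$fully_ramped)
  # a flat profile degenerates to near-tip breakpoints with ~zero residual
  flat <- trapezoid_profile(L = 270, xi0 = 55, plateau = 0.6)
  flat$mean_abs_v <- rep(0.6, nrow(flat))
  ffit <- fit_changepoints(flat)
  expect_lt(ffit$sse, 1e-18)
  expect_lte(ffit$xi0_left, 5)
  expect_lte(ffit$xi0_right, 5)
})

test_that("change-point recovery tolerates SEM-scale noise", {
  set.seed(99)
  hits <- 0
  for (r in 1:100) {
    prof <- trapezoid_profile(L = 270, xi0 = 55, plateau = 0.6,
                              noise_sd = 0.03)
    fit <- fit_changepoints(prof)
    if (abs(fit$xi0_left - 55) <= 10 && abs(fit$xi0_right - 55) <= 10)
      hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("speed distributions are normalized and concentrate where expected", {
  ens <- generate_ensemble(generator_params(), n_cells = 20,
                           lane_lengths = 170, seed = 12)
  sd1 <- speed_distribution(ens$tracks)
  expect_equal(sum(sd1$density) * diff(sd1$mid[1:2]), 1, tolerance = 1e-9)
  # mass concentrates near the run speed and near zero (pauses)
  near_run <- sum(sd1$density[abs(sd1$mid - 0.62) < 0.15])
  near_zero <- sum(sd1$density[sd1$mid < 0.15])
  elsewhere <- sum(sd1$density[sd1$mid > 0.9])
  expect_gt(near_run + near_zero, 4 * elsewhere)
  # all-zero velocities produce a single spike at zero
  tr0 <- lane_trajectory(seq(0, 100, 10), rep(0, 11))
  sd0 <- speed_distribution(tr0)
  expect_identical(which(sd0$count > 0), 1L)
})

test_that("spectral peak sits at the fundamental of a triangle wave", {
  T0 <- 480
  t <- seq(0, 2160, 10)
  koor <- 60 * (2 / pi) * asin(sin(2 * pi * t / T0))
  tr <- lane_trajectory(t, koor, lane_length = 170)
  sp <- velocity_spectrum(list(tr, tr))
  m <- length(t) - 1
  expect_lte(abs(sp$f_max - 1 / T0), 1 / (m * 10))
  expect_equal(sp$period_T, 1 / sp$f_max / 60)
  # white-noise velocities: no sharp peak; flagged or flat
  set.seed(2)
  trn <- lane_trajectory(t, cumsum(rnorm(length(t))), lane_length = 170)
  spn <- velocity_spectrum(list(trn))
  expect_true(!spn$fitted ||
                max(spn$mean_amplitude) < 3 * stats::median(spn$mean_amplitude))
})

test_that("period-length regression is exact on exact lines", {
  L <- c(120, 170, 220, 270)
  d <- data.frame(lane_length = L, period = 0.054 * (L - 29.4))
  fit <- period_vs_length(d)
  expect_equal(fit$slope, 0.054, tolerance = 1e-12)
  expect_equal(fit$x_intercept, 29.4, tolerance = 1e-9)
  expect_equal(fit$v_c, 2 / 0.054 / 60, tolerance = 1e-12)
  expect_equal(sum(stats::residuals(fit$fit)^2), 0, tolerance = 1e-20)
  expect_error(period_vs_length(d[1:2, ]), "at least 3")
})

test_that("period-length slope is robust to jitter", {
  set.seed(17)
  L <- c(120, 170, 220, 270)
  hits <- 0
  for (r in 1:100) {
    d <- data.frame(lane_length = L,
                    period = 0.054 * (L - 29.4) * (1 + runif(4, -0.05, 0.05)))
    fit <- period_vs_length(d)
    if (abs(fit$slope - 0.054) / 0.054 <= 0.10) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("reversal events are censoring-aware region occupancies", {
  region <- reversal_region(170, 55)
  t <- seq(0, 400, 10)
  koor <- rep(0, length(t))
  koor[t >= 100 & t <= 200] <- 50        # inside right region [30, 85]
  tr <- lane_trajectory(t, koor, lane_length = 170)
  ev <- detect_reversals(tr, region)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$t1, 100)
  expect_equal(ev$t2, 210)
  expect_equal(ev$t_R, 110)
  expect_identical(ev$tip, "right")
  # never entering -> no events
  expect_identical(nrow(detect_reversals(
    lane_trajectory(t, rep(0, length(t)), lane_length = 170), region)), 0L)
  # interval open at the record end is censored
  koor2 <- rep(0, length(t)); koor2[t >= 300] <- 50
  ev2 <- detect_reversals(lane_trajectory(t, koor2, lane_length = 170), region)
  expect_identical(nrow(ev2), 0L)
})

test_that("reversal-time distributions are invariant under lane length", {
  p <- generator_params()
  ens <- generate_ensemble(p, n_cells = 60, lane_lengths = c(120, 270),
                           seed = 5)
  pool <- function(L) {
    sel <- ens$tracks[vapply(ens$tracks, function(t)
      attr(t, "lane_length") == L, TRUE)]
    region <- reversal_region(L, 55)
    unlist(lapply(sel, function(t) detect_reversals(t, region)$t_R))
  }
  a <- pool(120); b <- pool(270)
  ks <- suppressWarnings(stats::ks.test(a, b)$statistic)
  expect_lt(unname(ks), 0.1)
})

test_that("kymographs encode position and motion", {
  # stationary bump -> constant stripe over time
  nx <- 40; nt <- 30
  arr <- array(0, c(nx, 5, nt))
  arr[18:22, 2:4, ] <- 1
  km <- kymograph(arr)
  expect_true(all(apply(km, 1, function(r) length(unique(r)) == 1)))
  # moving bump -> band with the imposed slope
  arr2 <- array(0, c(nx, 5, nt))
  for (k in 1:nt) arr2[(k):(k + 3), 2:4, k] <- 1
  km2 <- kymograph(arr2)
  pos <- apply(km2, 2, function(cl) mean(which(cl > 0)))
  slope <- stats::coef(stats::lm(pos ~ seq_len(nt)))[2]
  expect_equal(unname(slope), 1, tolerance = 1e-6)
})

test_that("cycle periods satisfy the kinematic consistency identity", {
  # short deceleration ramp: the constant-speed identity neglects the ramp
  # traversals, which contribute 4 * (ramp_xi - turn_point) / v_run per cycle
  p <- generator_params(duration = 10080, turn_point = 50)
  set.seed(30)
  cyc <- c()
  for (k in 1:20) {
    pk <- p; pk$seed <- sample.int(1e6, 1)
    tr <- generate_trajectory(pk)
    turns <- attr(tr, "truth")$turns
    right <- turns$t_arrive[turns$side == "right"]
    if (length(right) >= 2) cyc <- c(cyc, diff(right))
  }
  travel_approx <- 2 * (p$lane_length - 2 * p$turn_point) / p$v_run +
    2 * p$pause_mean
  expect_lt(abs(mean(cyc) - travel_approx) / travel_approx, 0.15)
})
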