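test_that("hamiltonian matches closed forms for tiny cells", {
  p <- model_params()
  occ1 <- matrix(FALSE, 5, 5); occ1[3, 3] <- TRUE
  st1 <- manual_state(occ1, p)
  expect_equal(hamiltonian(st1, p),
               p$kappa_A * 16 + p$kappa_P * 64 - p$eps0)   # A = 4, P = 8
  occ2 <- matrix(FALSE, 5, 5); occ2[3:4, 3:4] <- TRUE
  st2 <- manual_state(occ2, p)
  expect_equal(hamiltonian(st2, p),
               p$kappa_A * 256 + p$kappa_P * 256 - 4 * p$eps0) # A = 16, P = 16
  expect_error(hamiltonian(manual_state(matrix(FALSE, 3, 3), p), p), "empty")
})

test_that("R and compiled Hamiltonians agree on random states", {
  p <- model_params()
  m <- default_round_mask()
  set.seed(21)
  st <- init_cell_state(m, p)
  st$eps[st$occ] <- runif(sum(st$occ), p$eps0 - p$delta_eps / 2,
                          p$eps0 + p$delta_eps / 2)
  expect_equal(
    hamiltonian(st, p),
    microlane:::cpp_hamiltonian(m$grid, st$occ,
                                microlane:::.cpm_eps_filled(st, p),
                                microlane:::.params_list(p)),
    tolerance = 1e-12)
})

test_that("incremental dH bookkeeping equals full recomputation over >= 1e4 moves", {
  p <- model_params()
  m <- default_round_mask()
  pl <- microlane:::.params_list(p)
  set.seed(31)
  st <- init_cell_state(m, p)
  occ <- st$occ
  eps <- microlane:::.cpm_eps_filled(st, p)
  # randomized field in bounds makes the move population diverse
  eps[occ] <- runif(sum(occ), p$eps0 - p$delta_eps / 2, p$eps0 + p$delta_eps / 2)
  n_acc <- 0; max_err <- 0
  while (n_acc < 10000) {
    H0 <- hamiltonian(structure(list(occ = occ, eps = ifelse(occ, eps, NA),
                                     label = NULL, time = 0),
                                class = "cpm_state"), p)
    r <- microlane:::cpp_run_mcs(m$grid, occ, eps, pl, relax = FALSE)
    occ <- r$occ
    eps <- r$eps; eps[is.na(eps)] <- p$eps0
    H1 <- hamiltonian(structure(list(occ = occ, eps = ifelse(occ, r$eps, NA),
                                     label = NULL, time = 0),
                                class = "cpm_state"), p)
    max_err <- max(max_err, abs((H1 - H0) - r$dH_sum))
    n_acc <- n_acc + r$n_accepted
  }
  expect_gte(n_acc, 10000)
  expect_lt(max_err, 1e-9 * abs(hamiltonian(
    structure(list(occ = occ, eps = ifelse(occ, eps, NA), label = NULL,
                   time = 0), class = "cpm_state"), p)) + 1e-9)
})

test_that("protrusions never leave the adhesive mask", {
  p <- model_params()
  m <- make_mask(pattern_spec(60, 20, "round"))
  set.seed(5)
  st <- init_cell_state(m, p, area = 500)   # cell fills much of the short lane
  for (k in 1:400) {
    res <- attempt_step(st, m, p)
    st <- res$state
    if (isTRUE(res$accepted) && res$type == 1)
      expect_true(m$grid[res$site[1], res$site[2]])
  }
  expect_false(any(st$occ & !m$grid))
})

test_that("Metropolis acceptance frequency follows exp(-dH/kT)", {
  p <- model_params(kT = 1)
  m <- make_mask(pattern_spec(40, 16, "blunt"))
  occ <- matrix(FALSE, nrow(m$grid), ncol(m$grid))
  occ[9:12, 3:6] <- TRUE                       # 4x4 block mid-lane
  st0 <- manual_state(occ, p)
  set.seed(77)
  keys <- character(0); acc <- integer(0); trials <- integer(0)
  dHs <- numeric(0)
  for (k in 1:20000) {
    res <- attempt_step(st0, m, p)             # always from the same state
    if (!res$evaluated || !is.finite(res$dH) || res$dH <= 0) next
    key <- paste(res$type, res$site[1], res$site[2])
    i <- match(key, keys)
    if (is.na(i)) {
      keys <- c(keys, key); acc <- c(acc, 0L); trials <- c(trials, 0L)
      dHs <- c(dHs, res$dH)
      i <- length(keys)
    }
    trials[i] <- trials[i] + 1L
    acc[i] <- acc[i] + as.integer(res$accepted)
  }
  checked <- 0
  for (i in seq_along(keys)) {
    if (trials[i] < 300) next
    p_exp <- exp(-dHs[i] / p$kT)
    se <- sqrt(p_exp * (1 - p_exp) / trials[i])
    expect_lt(abs(acc[i] / trials[i] - p_exp), 3 * se + 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 2)
})

test_that("neighbourhood classification counts events within the signaling range", {
  p <- model_params(signaling_R = 4)           # 2 * spacing
  occ <- matrix(FALSE, 11, 9); occ[3:9, 3:7] <- TRUE
  st <- manual_state(occ, p)
  # no events -> all neutral
  cls <- classify_neighborhoods(st, p)
  expect_true(all(cls[st$occ] == 0L))
  # one protrusion event: exactly the sites within R are protrusive
  st$label[6, 5] <- 1L
  cls <- classify_neighborhoods(st, p)
  for (idx in which(st$occ)) {
    i <- (idx - 1) %% 11 + 1; j <- (idx - 1) %/% 11 + 1
    d <- sqrt((i - 6)^2 + (j - 5)^2) * p$spacing
    expect_identical(cls[i, j], if (d <= p$signaling_R) 1L else 0L)
  }
  # balanced events within range tie out to neutral
  st$label[6, 4] <- -1L
  cls <- classify_neighborhoods(st, p)
  expect_identical(cls[6, 5], 0L)   # sees both events, tie
})

test_that("polarization relaxation follows the exact exponential update", {
  p <- model_params(eps0 = 1, delta_eps = 1, mu = 0.1)
  occ <- matrix(FALSE, 3, 3); occ[2, 2] <- TRUE
  st <- manual_state(occ, p, eps_value = 1.0)
  cls <- matrix(NA_integer_, 3, 3); cls[2, 2] <- 1L
  st2 <- update_polarization(st, cls, p, dt = 1)
  expect_equal(st2$eps[2, 2], 1.5 - 0.5 * exp(-0.1), tolerance = 1e-12)
  # fixed point: already at target
  st$eps[2, 2] <- 1.5
  expect_equal(update_polarization(st, cls, p, dt = 1)$eps[2, 2], 1.5)
  # saturation for mu * dt large
  st$eps[2, 2] <- 1.0
  expect_equal(update_polarization(st, cls, p, dt = 1e6)$eps[2, 2], 1.5,
               tolerance = 1e-12)
  # retracting and neutral targets
  cls[2, 2] <- -1L
  expect_lt(update_polarization(st, cls, p, dt = 1)$eps[2, 2], 1.0)
})

test_that("compiled per-MCS relaxation agrees with the R classification + update", {
  p <- model_params()
  m <- default_round_mask()
  pl <- microlane:::.params_list(p)
  st <- init_cell_state(m, p)
  occ <- st$occ; eps <- microlane:::.cpm_eps_filled(st, p)
  set.seed(13)
  eps[occ] <- runif(sum(occ), p$eps0 - p$delta_eps / 2, p$eps0 + p$delta_eps / 2)
  for (rep in 1:5) {
    seed <- 1000 + rep
    set.seed(seed)
    r_no <- microlane:::cpp_run_mcs(m$grid, occ, eps, pl, relax = FALSE)
    set.seed(seed)
    r_yes <- microlane:::cpp_run_mcs(m$grid, occ, eps, pl, relax = TRUE)
    expect_identical(r_no$occ, r_yes$occ)      # same move sequence
    st_mid <- structure(list(occ = r_no$occ, eps = r_no$eps,
                             label = r_no$label, time = 0),
                        class = "cpm_state")
    cls <- classify_neighborhoods(st_mid, p)
    st_rel <- update_polarization(st_mid, cls, p, dt = p$mcs_minutes)
    expect_equal(st_rel$eps, r_yes$eps, tolerance = 1e-12)
    occ <- r_yes$occ
    eps <- r_yes$eps; eps[is.na(eps)] <- p$eps0
  }
})

test_that("simulations are reproducible, bounded and keep the cell whole", {
  p <- model_params()
  m <- default_round_mask()
  s1 <- run_simulation(m, p, duration = 720, sampling = 10, burn_in = 120,
                       seed = 9, check_bounds = TRUE, record_shapes = TRUE)
  s2 <- run_simulation(m, p, duration = 720, sampling = 10, burn_in = 120,
                       seed = 9)
  expect_identical(s1$trajectory$koor, s2$trajectory$koor)  # determinism
  # polarization bounds were asserted every MCS by check_bounds = TRUE;
  # also verify on the final state
  eps <- s1$state$eps[s1$state$occ]
  expect_true(all(eps >= p$eps0 - p$delta_eps / 2 - 1e-9))
  expect_true(all(eps <= p$eps0 + p$delta_eps / 2 + 1e-9))
  # single 4-connected component inside the mask at every sample
  for (shape in s1$shape_series) {
    expect_identical(n_components(shape), 1L)
    expect_false(any(shape & !m$grid))
  }
})

test_that("steady-state area is stable and polarized cells are front-heavy", {
  p <- model_params()
  m <- default_round_mask()
  sim <- run_simulation(m, p, duration = 2160, sampling = 10, burn_in = 240,
                        seed = 9)
  expect_lt(stats::sd(sim$area) / mean(sim$area), 0.10)
  v <- abs(diff(sim$trajectory$koor) / 10)
  moving <- which(v > 0.3) + 1
  wl <- sim$width_lead[moving]; wt <- sim$width_trail[moving]
  expect_gt(mean(wl, na.rm = TRUE), mean(wt, na.rm = TRUE))
})

test_that("without polarization feedback the motion is unpolarized", {
  p <- model_params()
  p$delta_eps <- 0
  m <- default_round_mask()
  vbar <- vapply(1:3, function(s) {
    sim <- run_simulation(m, p, duration = 1440, sampling = 10, burn_in = 240,
                          seed = s)
    mean(diff(sim$trajectory$koor) / 10)
  }, 0)
  expect_true(all(abs(vbar) < 0.05))
  # and the excursion stays far from pole-to-pole range
  sim <- run_simulation(m, p, duration = 1440, sampling = 10, burn_in = 240,
                        seed = 1)
  expect_lt(diff(range(sim$trajectory$koor)), 60)
})

test_that("MCS-duration calibration scales inversely with the target speed", {
  p <- model_params()
  m <- default_round_mask()
  c1 <- calibrate_mcs_duration(m, p, target_speed = 0.6, iterations = 1,
                               n_cells = 1, duration = 1440, seed = 3)
  c2 <- calibrate_mcs_duration(m, p, target_speed = 1.2, iterations = 1,
                               n_cells = 1, duration = 1440, seed = 3)
  expect_equal(c1$mcs_minutes / c2$mcs_minutes, 2, tolerance = 1e-9)
  p0 <- model_params(); p0$delta_eps <- 0
  expect_error(calibrate_mcs_duration(m, p0), "delta_eps")
})

test_that("calibrated model reproduces the target plateau speed", {
  p <- model_params()
  m <- default_round_mask()
  pc <- calibrate_mcs_duration(m, p, target_speed = 0.6, seed = 11)
  vs <- vapply(1:8, function(s) {
    sim <- run_simulation(m, pc, duration = 2160, sampling = 10,
                          burn_in = 240, seed = 400 + s)
    tr <- sim$trajectory
    v <- diff(tr$koor) / 10
    sel <- abs(tr$koor[-nrow(tr)]) < 30 & abs(tr$koor[-1]) < 30
    mean(abs(v[sel]))
  }, 0)
  expect_lt(abs(mean(vs) - 0.6) / 0.6, 0.10)
})
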