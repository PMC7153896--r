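# shared fixtures and small utilities built in code

default_round_mask <- function(L = 170) make_mask(pattern_spec(L, 20, "round"))

# flood fill over TRUE sites, 4-connectivity; returns number of components
n_components <- function(grid) {
  lab <- matrix(0L, nrow(grid), ncol(grid))
  comp <- 0L
  for (start in which(grid)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    while (length(stack) > 0) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[s] != 0L) next
      lab[s] <- comp
      i <- (s - 1L) %% nrow(grid) + 1L
      j <- (s - 1L) %/% nrow(grid) + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(grid) && jj >= 1 && jj <= ncol(grid) &&
            grid[ii, jj] && lab[ii, jj] == 0L)
          stack <- c(stack, (jj - 1L) * nrow(grid) + ii)
      }
    }
  }
  comp
}

# a cpm_state built by hand from an occupancy matrix (eps defaults to eps0)
manual_state <- function(occ, params, eps_value = params$eps0) {
  eps <- matrix(NA_real_, nrow(occ), ncol(occ))
  eps[occ] <- eps_value
  structure(list(occ = occ, eps = eps,
                 label = matrix(0L, nrow(occ), ncol(occ)), time = 0),
            class = "cpm_state")
}

# noiseless trapezoid spatial profile with given ramp width, as produced by
# spatial_profiles() (bin centers on the 5-um grid)
trapezoid_profile <- function(L = 270, xi0 = 55, plateau = 0.6, bin = 5,
                              tip_frac = 0.1, noise_sd = 0) {
  nbin <- ceiling(L / bin)
  centers <- seq(-nbin * bin / 2 + bin / 2, nbin * bin / 2 - bin / 2, by = bin)
  v <- vapply(centers, function(x) {
    d <- L / 2 - abs(x)                 # distance from nearest tip
    if (d >= xi0) plateau
    else plateau * (tip_frac + (1 - tip_frac) * d / xi0)
  }, 0)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  structure(data.frame(bin_center = centers, p = rep(1 / nbin, nbin),
                       mean_abs_v = v, sem = 0.03, n_pos = 100, n_v = 100),
            lane_length = L, bin_width = bin,
            class = c("spatial_profile", "data.frame"))
}

# study-condition synthetic ensemble + pipeline report, computed once and
# shared by several acceptance checks
.acc_cache <- new.env(parent = emptyenv())
acceptance_report <- function() {
  if (is.null(.acc_cache$report)) {
    ens <- generate_ensemble(generator_params(), n_cells = 100, seed = 42)
    .acc_cache$ensemble <- ens
    .acc_cache$report <- run_pipeline(ens, xi0 = 55)
  }
  .acc_cache$report
}
acceptance_ensemble <- function() {
  acceptance_report()
  .acc_cache$ensemble
}
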