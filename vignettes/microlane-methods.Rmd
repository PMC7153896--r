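---
title: "Modelling and quantifying quasi-periodic cell migration on microlanes"
author: "microlane authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying quasi-periodic cell migration on microlanes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Single cells confined to stripe-shaped adhesive micropatterns ("microlanes",
fibronectin stripes surrounded by a PEGylated, cell-repellent surface) migrate
in a striking quasi-periodic mode: they polarize, run to one end of the lane,
stall and depolarize when the leading lamellipodium meets the repellent
border, then spontaneously repolarize and run back. This package implements
both sides of the study of that phenomenology at desk scale: a lattice model
of the migrating cell and the complete trajectory-quantification pipeline used
on nucleus-tracking data, together with a synthetic trajectory generator that
provides ground truth for validating the pipeline.

## The extended Cellular Potts model

The cell's substrate contact area is a 4-connected set of occupied sites on a
2D square lattice (2 µm per site by default), strictly confined to the
adhesive mask. Writing $A$ for the contact area and $P$ for the contour
length, each configuration carries the energy

$$H = \kappa_A A^2 + \kappa_P P^2 - \sum_{\mathbf{x}} \epsilon(\mathbf{x}, t),$$

where the sum runs over occupied sites and $\epsilon(\mathbf{x}, t) \in
[\epsilon_0 - \Delta\epsilon/2,\; \epsilon_0 + \Delta\epsilon/2]$ is a
per-site *polarization field* standing in for local protrusive capability
(actin polymerization, contractility and adhesion). The cell evolves by
single-site Metropolis kinetics: an elementary event adds (protrusion) or
removes (retraction) one boundary site and is accepted with probability
$\min(1, e^{-\Delta H / kT})$. Protrusions onto non-adhesive sites are never
accepted; removals that would disconnect or empty the cell are rejected. A
newly added site inherits the $\epsilon$ value of the occupied neighbour that
sourced the protrusion, preserving spatial continuity of the field.

Polarity arises through two feedback loops that break detailed balance. After
every Monte Carlo step (MCS; on average one attempted event per boundary
site), each occupied site is classified by the balance of accepted protrusion
and retraction events within a Euclidean signaling range $R$:

* more protrusions than retractions — the field grows,
  $\partial_t \epsilon = \mu[\epsilon_0 + \Delta\epsilon/2 - \epsilon]$;
* more retractions than protrusions — the field decays,
  $\partial_t \epsilon = \mu[\epsilon_0 - \Delta\epsilon/2 - \epsilon]$;
* otherwise (ties included) it relaxes to rest,
  $\partial_t \epsilon = \mu[\epsilon_0 - \epsilon]$.

The update is applied as the exact exponential step
$\epsilon \leftarrow \epsilon_{\mathrm{target}} + (\epsilon -
\epsilon_{\mathrm{target}})\,e^{-\mu\,\Delta t}$ with $\Delta t$ one MCS
duration, so the bounds are preserved without clipping artifacts. High-$\epsilon$
regions protrude more cheaply and retract more expensively, so a protrusion
fluctuation self-amplifies into a stable leading edge while the opposite edge
becomes a retracting rear — a polarized, persistently migrating cell. At a
lane tip the front cannot advance, protrusion events cease, the front field
relaxes and the cell depolarizes; a new front then nucleates stochastically,
usually at the free edge, which is the model's account of the stochastic
reversal time.

### Parameters

| parameter | units | default | role |
|---|---|---|---|
| `kappa_A` | energy·µm⁻⁴ | 5.5e-4 | area stiffness; with `eps0` sets the steady-state area |
| `kappa_P` | energy·µm⁻² | 5e-4 | contour smoothness / effective membrane tension |
| `eps0` | energy/site | 3.3 | resting polarization; marginal gain per added site |
| `delta_eps` | energy/site | 9 | polarization range; front–rear contrast and persistence |
| `mu` | min⁻¹ | 0.2 | field relaxation rate (≈5-min polarity memory) |
| `signaling_R` | µm | 5 | spatial coherence of the feedback (small vs lane width) |
| `kT` | energy | 0.2 | Metropolis temperature; shape fluctuation level |
| `mcs_minutes` | min/MCS | 0.23 | physical duration of one MCS (calibrated) |
| `spacing` | µm/site | 2 | lattice resolution (lane width = 10 sites) |

No published parameter table was available for this model variant, so the
defaults are this package's own choices, fixed by three requirements: (i) the
steady-state contact area is ~700–750 µm², giving a polarized cell length of
roughly 45–55 µm on a 20-µm lane (cells in micrographs span about half of a
120-µm lane); (ii) the calibrated plateau speed is 0.6 µm/min; and (iii) the
reversal-time distribution on a 170-µm round-tip lane, extracted exactly as
for the experimental data (55-µm tip regions, 10-min sampling, 20-min
histogram bins), peaks near 100 min. The balance
$A^* \approx \epsilon_0 / (2\kappa_A h^2)$ predicts the steady area; `kT` and
`delta_eps` jointly set how rarely a polarized cell flips direction
spontaneously in mid-lane.

Two discretization details matter. First, the classification window is one
MCS, so the dynamics are fully determined by the per-MCS relaxation factor
$\mu \cdot \texttt{mcs\_minutes}$; `calibrate_mcs_duration()` therefore
rescales `mu` together with `mcs_minutes`, making speed calibration a pure
relabelling of physical time (rescaling `mcs_minutes` alone would change the
model's kinetics and the calibration fixed point becomes unstable). Second,
the connectivity guard on removals is a local 3×3 articulation check: it can
occasionally reject a globally safe removal, but it can never allow a
fragmenting one, and it keeps the kernel O(1) per event.

### Calibration and simulation protocol

```{r}
library(microlane)
mask <- make_mask(pattern_spec(170, 20, "round"))
params <- calibrate_mcs_duration(mask, model_params(), target_speed = 0.6)
sim <- run_simulation(mask, params, duration = 2160, sampling = 10,
                      burn_in = 240, seed = 1, record_fields = TRUE)
km <- kymograph(sim)    # polarization-field kymograph: zigzag band
```

Runs start from a compact disc at the lane centre with $\epsilon \equiv
\epsilon_0$; a 240-min burn-in window (polarization onset) is discarded. The
centre of mass along the lane ("koor", µm from the lane centre) is recorded
every 10 min for 36 h, mirroring the time-lapse experiments. Sampling times
are realized on the MCS grid (the nearest step at or after each nominal
time); at ~0.28 min/MCS the misalignment is negligible. One 36-h cell takes
well under a second on one core, so the ensembles used in the tests
(30+ cells) run in seconds.

## The quantification pipeline

The pipeline consumes uniformly sampled 1D trajectories (10-min default) and
mirrors the experimental analysis chain:

1. **Projection and centring** (`project_and_center`): only the long-axis
   component is kept; each track's lane centre is the midpoint of its two
   extreme excursions (the closest approaches to either tip), with a fallback
   to the mask centre for tracks that never explore the lane.
2. **Filtering** (`filter_tracks`): tracks shorter than 36 h, tracks that do
   not visit both tip regions ("explored the whole stripe"), and non-moving
   tracks are excluded, with a per-reason report.
3. **Velocities** (`instantaneous_velocity`): forward differences
   $v(t) = [x(t+\Delta t) - x(t)]/\Delta t$.
4. **Spatial profiles** (`spatial_profiles`): positions binned into 5-µm
   sections; per bin the occupancy fraction $p(x)$ and mean absolute velocity
   with its standard error. Velocities are assigned to the bin of the
   interval's *start* position; empty bins report `NA`, never zero.
5. **Change-point fit** (`fit_changepoints`): a continuous
   ramp–plateau–ramp (trapezoid) model is fitted to the speed profile by
   exhaustive least squares over all breakpoint pairs on the bin grid (at
   most a few dozen bins, so the search is exact and deterministic); for each
   pair the plateau level has a closed form. The ramps are constrained to
   start at the outermost observed bin values, ties are broken towards
   smaller tip distances, and the tip-to-breakpoint distance is reported as
   $\xi_0$ per tip. Profiles whose breakpoints meet are flagged "fully
   ramped" — the regime of lanes too short for a run phase.
6. **Speed distribution** (`speed_distribution`): density-normalized |v|
   histogram; for migrating ensembles its tail is close to exponential.
7. **Velocity spectrum** (`velocity_spectrum`): per cell, the magnitude of
   the DFT of the *signed* velocity series after mean removal (no window, no
   detrending beyond the mean, cells truncated to the common length); spectra
   averaged over cells, zero-frequency bin excluded; a scaled log-normal
   curve is fitted by nonlinear least squares and the dominant frequency
   $f_{\max}$ is the mode of the fitted curve, interpolating below the raw
   bin resolution. The migration period is $T = 1/f_{\max}$. If the fit fails
   or peaks outside the resolved band, the raw argmax is used and flagged.
8. **Period versus length** (`period_vs_length`): ordinary least squares of
   $T$ (h) on $L$ (µm). For a shuttling cell with length-independent
   reversal time, $T = (2/v_c)L + \text{const}$, so the crawling speed is
   $v_c = 2/\text{slope}$ and the x-intercept estimates the minimum lane
   length supporting oscillation.
9. **Reversal times** (`detect_reversals`): with tip regions within
   $\xi_0 = 55$ µm of either tip (the change-point scale of the experimental
   profiles), a reversal event is a maximal run of samples inside one
   region; $t_1$ is the first sample inside, $t_2$ the first sample after
   exit, $t_R = t_2 - t_1$. Events open at either record end are censored
   and discarded. Events are counted whether or not the exit actually
   reverses direction (the definition is purely geometric); a `reversed`
   flag supports sensitivity analyses.
10. **Kymographs** (`kymograph`): the polarization field (or occupancy)
    collapsed over the lane's short axis by taking the maximum, giving the
    position × time matrices in which pole-to-pole migration appears as a
    zigzag band.

`run_pipeline()` chains 2–9 per lane length, pools reversal statistics,
regresses period on length when at least three lengths are present (and
otherwise says so in a notice), and optionally writes all tables plus a JSON
metadata sidecar recording parameters and seed.

## The synthetic trajectory generator

`generate_trajectory()` emulates the pole-to-pole phenomenology with fully
known ground truth so that every pipeline stage can be validated without
simulation runs: constant run speed `v_run` in the lane centre; from
`ramp_xi` (µm from the tip) inward a constant deceleration that brings the
cell to rest exactly at `turn_point`; a gamma-distributed stationary pause;
then the mirror-image acceleration back out. Samples are taken every 10 min
with additive Gaussian noise (1 µm). A linear-in-position speed taper would
make the arrival time diverge logarithmically, which is why the ramp is
linear in time; its traversal takes exactly
$2(\texttt{ramp\_xi} - \texttt{turn\_point})/v_{\mathrm{run}}$.

The defaults encode the reported summary statistics of the microlane
experiments they emulate: `v_run = 0.62` µm/min (the crawling speed implied by the
period–length slope of 0.054 h/µm), `ramp_xi = 55` µm (the change-point
distance), and a 13-µm ramp with a gamma(shape 4, mean 33 min) pause. The
last two were chosen jointly *before* any test was run, because the reported
values over-determine the kinematics: a mean reversal time of exactly
100 min with $v_c = 0.62$ µm/min implies a period–length x-intercept of
$2\xi_0 - v_c \cdot t_R \approx 48$ µm, while the reported intercept of
29.4 µm implies $t_R \approx 130$ min. The defaults sit at the compromise
$t_R = 116.9$ min / intercept 37.5 µm, which honours both reported values
within their reporting precision. The gamma family and its shape are fixture
choices (positively skewed pause distributions); the pause can be re-derived
for any target reversal time with `pause_for_target_reversal_time()`.

What the generator deliberately does **not** emulate: 2D shape dynamics, the
polarization field, cell-to-cell parameter variability, early reversals that
never reach the tip, track loss, or division. Pipeline tests passing on
synthetic ensembles therefore demonstrate estimator correctness on clean
quasi-periodic kinematics — not robustness to every artifact of live-cell
data.

## Numerical choices and degenerate inputs

* **Rasterization** is a centre-of-site inclusion test on a grid sized so
  every mask is mirror-symmetric about both lane midlines. The sharp tip's
  default half-angle is 55°: a 45° edge on a 2-µm grid passes exactly
  through site centres, a degenerate alignment that biases the raster area
  by about 1%; at 55° all four equal-area tip shapes agree in site count.
* **Change-point ties** go to the smaller $\xi_0$; a perfectly flat profile
  therefore yields near-tip breakpoints with zero residual rather than an
  arbitrary interior solution.
* **Spectral fits** start from moment-based log-normal initials; the fitted
  peak must lie inside the resolved frequency band or the raw argmax is used
  (flagged).
* **Reversal detection** with $\xi_0 = 0$ yields no events; lanes with
  $\xi_0 \ge L/2$ are rejected (the whole lane would be reversal region —
  the regime of lanes too short for directed migration).
* **Degenerate tracks** (no long-axis motion, never exploring the lane)
  are flagged during centring and removed by the filter rules rather than
  propagating `NaN`s.

### Problem sizes used by the tests

The test-suite study conditions are: synthetic ensembles of 100 cells per
lane length at lengths 120/170/220/270 µm, 36 h per track at 10-min sampling
(matching the experimental design of roughly 100 tracked cells per length);
simulation checks use 32 calibrated cells of 36 h on the 170-µm round-tip
lane. The invariant suites use 10⁴+ accepted Metropolis moves for the
energy-bookkeeping check and 100-replicate Monte Carlo runs for estimator
recovery.

## Known limitations

* The model keeps the mean polarization $\epsilon_0$ and hence the contact
  area constant; the experimental observation that spreading area shrinks
  upon depolarization is intentionally not modelled.
* Simulated cells are clonal: one parameter set per ensemble. Experimental
  reversal-time and velocity distributions are broader than simulated ones,
  so variance-sensitive comparisons should expect the simulation to
  underestimate spread.
* Cells are strictly confined to the mask; transient protrusions past the
  pattern border, which occur in experiments, are absent, and simulated
  contours conform less to concave/sharp tips than real cells do.
* The local articulation check is conservative; extremely tortuous shapes
  are slightly stiffer against retraction than an exact global check would
  make them.
* The spectral period estimator resolves frequencies to one DFT bin of a
  36-h record before interpolation by the log-normal fit; period estimates
  for very slow oscillators (lanes much longer than 270 µm) would need
  longer records.
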