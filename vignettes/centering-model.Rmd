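---
title: "A stochastic microtubule-pushing model of nucleus centering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic microtubule-pushing model of nucleus centering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcentering)
```

## The model

Interphase fission yeast centers its nucleus — and with it the spindle pole
body (SPB) that later dictates the division septum position — using pushing
forces generated by microtubule (MT) bundles polymerizing against the cell
tips. `mtcentering` implements this picture as an overdamped two-dimensional
model. The cell is a rectangle of length $2L$ and width $2R$; the nucleus is
a rigid circle of radius $r_{nuc}$ carrying MT nucleation sites (iMTOCs) on
its periphery, one of which (the most populated) is the SPB, fixed at anchor
angle $\psi = 0$ in the nucleus frame.

The nucleus obeys force and torque balance,

$$\zeta_T \dot{X} = \sum_i f_i, \qquad \zeta_R \dot\omega = \sum_i T_i,$$

with no thermal terms: the measured thermal displacement scale of the
nucleus is two orders of magnitude below the active one, so Brownian forces
are neglected throughout.

**Forces.** A growing filament pushes only while its tip is at or beyond the
end wall of its side ($x = \pm L$; side-wall contact is not modeled). The
magnitude is the smaller of

* the polymerization force from the force–velocity relation,
  $f_p = f_s (1 - V^+_f / V^+)$, where $V^+$ and $V^+_f$ are the free and
  contact growth velocities and $f_s$ the stall force; and
* the critical Euler buckling force
  $f_e = \max(\kappa\pi^2/l^2,\ \kappa\pi^2/l_0^2)$, where $\kappa$ is the
  flexural rigidity and $l_0$ the anchor-to-wall distance frozen at the
  first contact of the growth excursion. The floor emulates the geometric
  confinement of buckled filaments: the pushing force never decays below its
  value at contact while the tip keeps elongating.

At the calibrated defaults $f_e < f_p$ for any filament long enough to reach
the wall of a wild-type-like cell, so pushing is buckling-limited, consistent
with the bent filaments seen in cells.

**Drag.** The nucleus is a Stokes sphere ($\zeta^T_{nuc} = 6\pi\eta r_{nuc}$,
$\zeta^R_{nuc} = 8\pi\eta r_{nuc}^3$). The attached filaments contribute
anisotropic slender-body drag, evaluated for the longest filament per anchor
and combined with the nucleus drag in series,
$1/\zeta_T = 1/\zeta^T_{nuc} + 1/\zeta^T_{MT}$, per axis (parallel and
perpendicular to the long axis). Projected lengths use $|\cos\theta|$ and
$|\sin\theta|$; a term whose slender-body logarithm is not positive is
outside the theory's validity and is dropped rather than allowed to
contribute negative drag. With no filaments the combination reduces to the
nucleus drag alone.

**Catastrophe statistics.** Catastrophe times are gamma distributed with
step parameter $N$ and timescale $T$; at $N = 1$ the model collapses to the
classical memoryless exponential. Pushing shortens catastrophe times through
$\tau(V^+_f) = \tau_0 + (\tau(V^+) - \tau_0)\, V^+_f / V^+$ with $\tau_0$
the stalled-growth mean catastrophe time.

The integrator reconciles the per-step hazard picture and the rescaled
drawn-time picture as follows (both are implemented):

* `clock` (default): at each rescue a catastrophe time $\tau^*$ is drawn
  from the gamma model and a clock advances at rate 1 during free growth and
  at rate $\max(1, \tau^*/\mathrm{rescaled}(\tau^*))$ during contact.
  This reproduces the per-filament mean relation exactly (the
  permanent-contact ensemble mean is $\tau_0 + (NT - \tau_0) V^+_f/V^+$,
  verified by a Monte-Carlo test). Drawn times at or below $\tau_0$ advance
  at rate 1: the rescaling law cannot shorten them further, and slowing the
  clock under load would be unphysical.
* `hazard`: the filament of age $a$ catastrophizes in a step of length
  $\Delta t$ with probability $1 - \exp(-\lambda \Delta t / \tau_T(a))$,
  where $\tau_T(a) = S(a)/p(a)$ is the inverse hazard of the gamma model,
  computed in log space. Since no drawn time exists here, the contact load
  factor $\lambda$ uses the mean-based ratio $NT/\mathrm{rescaled}(NT)$.

Whether the force rescaling acts on the hazard or on the drawn time is not
resolvable from first principles; the two modes agree in their free-growth
age distributions (Kolmogorov–Smirnov distance $< 0.01$ at $n = 10^5$,
tested) and differ only in the fine structure of contact dwell times.

Rescue is instantaneous at zero length; every rescue draws a fresh axis
angle from a zero-centered truncated normal on $(-\pi/2, \pi/2)$.

**Integration.** A two-step scheme: a Monte-Carlo step evolves every
filament (growth, shrinkage, catastrophe, rescue), then a forward-Euler step
updates $x$, $y$, $\omega$. Filament states, contact flags and forces are
evaluated on the pre-step configuration. The run starts with the nucleus at
the left cell tip and lasts 7200 s (one generation) by default.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| $2L$, $2R$ | 14, 3.5 | μm | cell length, width |
| $r_{nuc}$ | 1.4 | μm | nucleus radius |
| $\eta$ | 1 | pN·s/μm² | cytoplasmic viscosity (calibration default) |
| $r_{MT}$ | 0.0125 | μm | MT radius (slender-body drag) |
| $V^+$, $V^+_f$, $V^-$ | 0.05, 0.017, 0.15 | μm/s | growth, contact, shrinkage velocities |
| $f_s$ | 5 | pN | stall force (within the 4–6 pN admissible band) |
| $\kappa$ | 1.25 | pN·μm² | flexural rigidity |
| $N$, $T$ | 3.6, 35 | –, s | gamma catastrophe parameters (Mal3 fit) |
| $\tau_0$ | 25 | s | stalled-growth mean catastrophe time |
| $N_r = N_l$ | 9 | – | MTs per side (18 total; bundles = quotient(18/4) = 4) |
| $\theta$ spread | 0.3 | rad | axis-angle scale (near-axial wild-type bundles) |
| dt | 0.05 | s | integration step |
| burn-in | 1800 | s | transient discarded before statistics |

The kinetic values are *calibration defaults*: the per-strain measured
velocities are not printed in any source available to this package, so these
are representative wild-type-like values, all config-overridable. The
burn-in is this package's choice: runs start at the cell tip, and the
fidelity statistics are intended to describe the stationary regime; 1800 s
is several times the slowest observed relaxation at the defaults. dt = 0.05
s keeps per-step displacements below 0.02 μm at the maximal force-to-drag
ratio; halving dt changes δ and σx by less than the replicate standard
error (tested; equality is assessed against the combined SEM of two
20-replicate sets).

## Fidelity statistics

For the post-burn-in longitudinal track $x(t)$ of the nucleus centroid:

* reliability $\delta = |\overline{x}|$ (the absolute value implements the
  convention of orienting each cell so its time-averaged displacement is
  positive);
* robustness $\sigma_x = \mathrm{sd}(x)$;
* standard errors by a moving-block bootstrap with block length equal to the
  autocorrelation time, estimated as the first $1/e$ crossing of the
  empirical ACF (the estimator is this package's choice; a constant series
  is defined to be fully correlated).

Statistics are computed on the **centroid**; the SPB track is recorded too.
With the SPB anchored at $\psi = 0$ and $\omega$ diffusing slowly, raw SPB
coordinates carry a quasi-constant $+r_{nuc}$ offset that would be removed
experimentally by per-cell orientation; the centroid avoids this artifact.
`sphere_projection_convolve()` maps a centroid distribution to the expected
SPB distribution by convolution with the axis projection of a uniform
sphere, which by Archimedes' theorem is uniform on $[-r_{nuc}, r_{nuc}]$.

The failure coefficient $\Phi$ approximates the position distribution as a
Gaussian $(\delta, \sigma_x)$ and integrates its mass beyond a failure
threshold $x_f$ (upper tail by default, matching the $\delta \ge 0$
convention; a two-sided variant is available). $x_f$ is the extreme-5%
quantile of the absolute wild-type septum offsets. The empirical counterpart
$S_f$ (fraction of septa beyond $x_f$) converges to $\Phi$ by the law of
large numbers, which the tests verify to $|S_f - \Phi| < 0.005$ at
$n = 10^5$.

## Bayesian inference of catastrophe-time distributions

Observed catastrophe events are windowed: only events inside $[a, b]$ are
measurable. The package fits the gamma model by

* maximum likelihood (`mle_fit`, log-parameter BFGS from moment starts), and
* a grid posterior on $N \in [1, 10]$, $T \in [10, 500]$ s (default steps
  0.05 and 1 s; the grid resolution is unstated in the source analysis and
  configurable here), with log-sum-exp normalization so the posterior never
  underflows.

The informative prior mixes the normalized likelihood surface of a Mal3
reference dataset with a uniform table, with the mixture weight chosen so
that the max/min prior probability ratio is 10. The ratio is a monotone
Möbius function of the weight, so the weight is solved in closed form
rather than by iterative root finding. Because the experimental Mal3 event
list is not distributed, the anchor surface defaults to a synthetic Mal3
calibration sample (n = 200, seeded); it is labeled synthetic throughout.

The grid likelihood is the *untruncated* gamma likelihood by default, with
truncation applied only when comparing fitted and empirical distributions
(`truncated_fit_check`, Kolmogorov–Smirnov distance plus a
parametric-bootstrap p value). A window-truncated likelihood is available
(`truncated = TRUE`) and is the statistically consistent choice when the
window removes noticeable mass; the default follows the full-distribution
workflow, and the recovery tests document the (small) resulting bias.

## Synthetic data

The generators stand in for the microscopy-derived inputs:

* `gen_catastrophe_times()` — gamma draws rejected into the observation
  window; Mal3 calibration default (3.6, 35 s, window 10–400 s; the window
  is a plausible reconstruction, configurable).
* `gen_spb_trajectory()` — a stationary AR(1) surrogate with specified mean
  offset, spread and autocorrelation time: the simplest process with the
  statistical structure the statistics layer assumes, so that layer is
  testable independently of the mechanistic simulator. It deliberately lacks
  the simulator's nonlinearities (wall clamps, discrete kicks), so passing
  statistics tests on it validates the estimators, not the mechanics.
* `gen_septum_offsets()` — $|\mathcal{N}(\delta,
  \sqrt{\sigma_x^2 + \sigma_{place}^2})|$; the placement noise (0.3 μm
  default, this package's choice) represents septum positioning error beyond
  the SPB spread.
* `gen_cell_lengths()` — truncated normal (mean 14 μm, sd 1 μm, bounds
  10–18 μm; sd and bounds are this package's reconstruction of natural
  length variation at mitotic onset).

All generators are reproducible from (parameters, n, seed) and restore the
caller's RNG state.

## Sweeps and the failure-coefficient map

`sweep_centering()` runs replicate simulations over cell lengths and MT
numbers with counter-derived seeds (reproducible and recomputable per cell)
and `reproduce_fig7_maps()` writes the δ, σx and Φ grids at desk scale
(6 lengths × 5 MT numbers × 20 replicates of 7200 s; ~10 minutes on one
CPU). The acceptance suite uses a 6-length × 20-replicate slice plus a
5-MT-number × 20-replicate slice; the δ-versus-length trend, which is
shallow relative to replicate noise, is estimated on 60 replicates per
length.

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
traj <- simulate_centering(cfg)
summarize_centering(traj)
sw <- sweep_centering(cfg, cell_lengths = c(10, 12, 14, 16, 18, 20),
                      mt_numbers = 18, replicates = 20)
aggregate(phi ~ length, sw, mean)
```

## Design choices and known limitations

* **Geometry conventions.** The tip of a side-$s$ filament is
  `anchor + l (s cosθ, sinθ)`; contact is tip-beyond-end-wall. The anchor
  co-rotates with the nucleus; the axis angle stays fixed in the world frame
  between rescues (whether filaments swivel with the nucleus is unstated in
  the underlying analysis; this is the simpler convention).
* **Correlated left/right mode.** "Perfect correlation of the left and right
  force generators" mirrors orientation, drawn catastrophe time *and*
  nucleation-site placement across the cell midplane. Orientation-only
  correlation does not reduce the replicate spread of δ, because δ is
  dominated by anchor-placement asymmetry; full mirroring halves both δ and
  its spread, and makes a mirror-initialized centered state an exact fixed
  point of the x dynamics (tested at machine precision).
* **Transverse confinement.** The nucleus is confined to
  $|y| \le R - r_{nuc}$ by the side walls; this geometric clamp is silent.
  The longitudinal clamp at $|x| = L - r_{nuc}$ is a numerical guard whose
  activation count is reported and is zero in healthy runs.
* **Failure-coefficient map.** Under the calibrated defaults, every
  univariate trend reproduces the expected structure (δ worsens with length
  beyond 14 μm and improves with MT number; σx improves with length and MT
  number; correlated mode narrows δ). The *composite* Φ map, however,
  attains its minimum at 18–20 μm rather than 14 μm at 18 MTs: the δ
  deterioration with length is too shallow (≈ 0.02 μm per μm of cell
  length) to outweigh the σx improvement. At the default growth velocity
  the mean filament excursion (6.3 μm) still yields re-centering contacts
  every ≈ 80 s per side even in 20 μm cells. Reproducing a 14 μm optimum
  would require the measured per-strain kinetics, which are not publicly
  printed; the calibrated defaults are retained rather than tuned to the
  map, and the corresponding acceptance check documents the discrepancy.
* Out of scope by design: thermal forces, permeable-sphere and
  confined-cylinder drag corrections, nucleus deformability, side-wall
  pushing, 3-D geometry, cell growth during a run, rescue before full
  depolymerization.
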