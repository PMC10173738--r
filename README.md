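# mtcentering

Stochastic simulation and analysis of microtubule-pushing-driven nucleus
centering in fission yeast.

At the onset of mitosis the fission yeast nucleus must sit at the cell
center, because the nucleus dictates where the division septum forms.
Centering is achieved by bundles of microtubules (MTs) nucleated on the
nuclear periphery that polymerize against the cell tips and push the nucleus
back toward the middle. This package is for quantitative cell biologists and
biophysicists who want to simulate that mechanism, score how well it works,
and infer MT catastrophe statistics from event data.

## What it implements

**Mechanistic model.** A 2-D overdamped model of a rigid nucleus (radius
*r<sub>nuc</sub>*) in a rectangular cell of length 2*L*: MTs undergo dynamic
instability with gamma-distributed catastrophe times
*P*(τ|N,T) = τ<sup>N−1</sup>e<sup>−τ/T</sup>/(T<sup>N</sup>Γ(N)), push only
while touching an end wall with force min(*f<sub>p</sub>*, *f<sub>e</sub>*)
— the polymerization force *f<sub>p</sub>* = *f<sub>s</sub>*(1 −
V<sup>+</sup><sub>f</sub>/V<sup>+</sup>) capped by the Euler buckling force
*f<sub>e</sub>* = κπ²/l² with a geometric floor — and experience
force-shortened catastrophe, τ(V<sup>+</sup><sub>f</sub>) = τ₀ +
(τ(V<sup>+</sup>) − τ₀)·V<sup>+</sup><sub>f</sub>/V<sup>+</sup>. Nucleus and
filament drags (Stokes sphere + anisotropic slender-body) combine in series.
The integrator is a two-step Monte-Carlo / forward-Euler scheme (C++ core,
bit-reproducible from a seed).

**Fidelity statistics.** Reliability δ = |mean(x)|, robustness σ<sub>x</sub>
= sd(x), standard errors by moving-block bootstrap with block =
autocorrelation time, stationarity checks, and the failure coefficient
Φ = A(&gt;x<sub>f</sub>)/A — the Gaussian-tail probability of the position
lying beyond a failure threshold x<sub>f</sub> (the extreme-5% quantile of
wild-type septum offsets) — plus its empirical counterpart S<sub>f</sub>
and feature Z-scores.

**Bayesian inference.** Gamma MLE and a grid posterior on N ∈ [1, 10],
T ∈ [10, 500] s with an informative prior built by mixing a Mal3-anchored
likelihood surface with a uniform table so that max/min prior probability
equals 10; window-truncated goodness-of-fit with parametric-bootstrap
p values.

**Synthetic data.** Seeded generators for window-truncated catastrophe
times, stationary AR(1) SPB trajectories, septum offsets and cell-length
populations — every tabular input the pipeline consumes.

## Worked example

```r
library(mtcentering)

cfg  <- sim_config(seed = 1)        # 14 um cell, 18 MTs, 7200 s
traj <- simulate_centering(cfg)
summarize_centering(traj)
#> centering summary (5401 samples)
#>   delta   = 0.8487 um (SE 0.0760)
#>   sigma_x = 0.6312 um (SE 0.0440)
#>   sigma_y = 0.2600 um
#>   autocorrelation time = 85.0 s
```

The nucleus, started at the cell tip, centers within the burn-in and then
fluctuates: this replicate sits on average 0.85 μm from the center
(reliability δ, with its moving-block bootstrap SE) and wanders with spread
0.63 μm (robustness σ<sub>x</sub>); successive positions decorrelate over
~85 s. Feeding δ and σ<sub>x</sub> to the failure coefficient gives the
probability of the nucleus lying beyond a threshold, e.g.
`failure_coefficient(0.39, 0.60, 1.5)` → `0.032`.

Inference on synthetic Mal3-like catastrophe events recovers the gamma
parameters:

```r
d <- gen_catastrophe_times(n = 1e4, seed = 42)  # Gamma(3.6, 35 s) in (10, 400) s
mle_fit(d)[c("shape", "scale")]
#> $shape 3.65  $scale 34.4
grid_posterior(d, prior = build_informative_prior(mal3_anchor_loglik()),
               truncated = TRUE)
#> posterior grid 181 x 491 (N in [1, 10], T in [10, 500] s)
#>   mode: N = 3.6, T = 35 s
```

Parameter sweeps over cell length and MT number (`sweep_centering()`,
`reproduce_fig7_maps()`) score δ, σ<sub>x</sub> and Φ across conditions;
a thin command-line wrapper with `simulate`, `sweep`, `stats`, `phi`, `sf`,
`fit-mle`, `fit-bayes`, `synth` and `reproduce-fig7` subcommands is
installed at `inst/cli/mtcenter`.

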