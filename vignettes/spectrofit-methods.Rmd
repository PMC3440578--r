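---
title: "Models and methods behind SpectroFit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind SpectroFit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpectroFit)
```

SpectroFit implements the analysis chain used to characterize small Fe-S
cluster proteins such as yeast Dre2 in solution. This vignette documents the
models, the numerical choices, and the design decisions — what is assumed,
what is tunable, and what the synthetic-data tests do and do not demonstrate
about real instrument data.

## TCSPC decays and iterative reconvolution

A TCSPC measurement histograms photon arrival times into channels of width
$\Delta t$ (default 0.01 ns, 4096 channels — a 41 ns window that
comfortably spans both a 0.16 ns and a 3.3 ns component). The measured
expectation is the convolution of the instrument response function (IRF)
with the decay law $I(t) = \sum_i \alpha_i e^{-t/\tau_i}$, plus a flat
background. `reconvolve()` evaluates this forward model: the IRF is
normalized (optionally shifted by a sub-channel amount via linear
interpolation), the exponentials are sampled at channel midpoints, and the
discrete convolution is computed by zero-padded FFT. The same code path
serves the generator (`simulateDecay()`, which adds Poisson noise) and every
fitter, so noiseless generator output is recovered exactly — that
generator–fitter consistency is the package's primary recovery oracle.

`fitDecay()` performs weighted least squares with the usual TCSPC Poisson
weights, variance $\max(y_j, 1)$ (the floor avoids zero-variance empty
channels). The fitted range starts at the IRF peak channel by default; the
rising edge enters through the convolution, which is what makes sub-ns
terms meaningful at all. Lifetimes are optimized by Levenberg–Marquardt on
$\log\tau$ with amplitudes profiled out by a non-negative weighted linear
solve. Because the likelihood surface of multi-exponential fits is
multimodal, the optimizer is multi-started deterministically: from the
supplied initial values if any, from two spreads around the mean arrival
time (one biased toward short lifetimes), from a wide logarithmic ladder,
and from the $(k-1)$-component solution augmented with one faster component
— the standard guard against the local minimum in which a sub-resolution
lifetime is absorbed by its neighbour.

Reporting rules make degenerate fits visible instead of hiding them:
components are returned sorted by lifetime; pairs closer than 5% are merged
with summed amplitude; lifetimes pinned at the search bounds with a
negligible photon share are dropped (an ultrafast term can soak up most of
the *amplitude* while contributing almost no photons — its amplitude is
meaningless); any of these conditions, or near-zero amplitudes, clears the
`converged` flag.

Two numerical artifacts of observed-count weighting are worth knowing.
First, reduced $\chi^2$ sits slightly below 1 on average (channels that
fluctuate low get too much weight), and recovered lifetimes carry a small
(<1%) downward bias at $10^7$ counts — well inside the reproducibility of
real measurements. Second, reduced $\chi^2$ is diluted when a large
fraction of channels is effectively empty; comparisons between nested fits
are more informative than the absolute value in that regime.

## Maximum-entropy lifetime distributions

`fitMEM()` inverts the decay onto a logarithmic lifetime grid (default 150
nodes over 0.01–30 ns, bracketing tryptophan lifetimes with margin) by
maximizing the Skilling–Jaynes entropy
$S = \sum_k [a_k - m_k - a_k \ln(a_k/m_k)]$ subject to
$\chi^2 \le \chi^2_\mathrm{target}$ (default: the number of fitted
channels, i.e. reduced $\chi^2$ of 1). Among all amplitude distributions
consistent with the data it returns the least committal one relative to the
prior $m$.

The solver minimizes $\tfrac12\chi^2 - \mu S$ on log-amplitudes (L-BFGS-B
with the analytic gradient, so positivity is structural), and exploits that
$\chi^2(\mu)$ is monotone increasing in $\mu$: starting from $\mu = 1$ it
walks $\mu$ down (or up) by decades with warm starts until the target is
bracketed, then bisects $\log\mu$ to
$|\chi^2 - \mathrm{target}|/\mathrm{target} < 10^{-3}$. Walking down from
the prior side matters: the $\mu \to 0$ problem is severely ill-conditioned
(adjacent grid columns are nearly collinear) and is only ever solved when
the data genuinely cannot reach the target, in which case the best-$\chi^2$
solution is returned flagged `"infeasible"`. Because the target equals the
*expected* $\chi^2$, individual noise realizations fluctuate around it; a
realization whose best $\chi^2$ lands just above the target is correctly
flagged while still lying inside the practical 0.8–1.2 band.

The default prior is flat with total mass two orders of magnitude below the
data scale. Grid nodes the data cannot constrain (e.g. lifetimes far below
the IRF width) relax to the prior level, so the prior total directly
controls how much spurious amplitude such nodes retain; two orders down
keeps them below 1% of the signal while staying large enough for the inner
solver to be well conditioned. If the prior already satisfies the
constraint — data with no decay information — the prior itself is returned
(status `"prior"`), which is the exact entropy maximum.

`extractComponents()` reduces a distribution to discrete components by
cutting at zero-density valleys (below $10^{-3}$ of the maximum by
default): each contiguous region contributes its summed, renormalized
weight as amplitude and its weight-weighted geometric mean as lifetime.

## Anisotropy and the wobbling cone

`simulatePolarized()` and `fitAnisotropy()` use the associative model: each
lifetime is associated with all rotational correlation times, so
$I_{vv} \propto I(t)[1 + 2r(t)]/3$ and
$I_{vh} \propto I(t)[1 - r(t)]/(3G)$ with
$r(t) = \sum_i \beta_i e^{-t/\theta_i}$. Fitting operates on the polarized
count histograms, not on the ratio $r(t)$, so Poisson weighting remains
valid. The correlation times are optimized on $\log\theta$ with the
$\beta_i$ as bounded parameters in $[0, 0.4]$ and the single overall scale
profiled analytically. The box on $\beta$ is part of the optimization
rather than a post-hoc clip because the model is weakly identified at low
counts: a slow rotor can trade off against the scale, inflating $\beta$
without bound if it is solved linearly. The generator defines
`totalCounts` as the average photon budget per detector, with one shared
scale for both so the vv/vh balance that encodes $r(t)$ is preserved.

The wobbling-in-cone semi-angle solves
$\beta_3/r_0 = [\tfrac12\cos\omega\,(1+\cos\omega)]^2$. With
$q = \sqrt{\beta_3/r_0}$ this is the quadratic $c^2 + c - 2q = 0$ in
$c = \cos\omega$, and `coneAngle()` uses its admissible root
$c = (-1 + \sqrt{1+8q})/2$, which maps $\beta_3 = r_0$ to 0° and
$\beta_3 = 0$ to 90°. The fundamental anisotropy defaults to
$r_0 = 0.185$, the tryptophan value at ~295–300 nm excitation. The
reference dataset includes one construct whose *measured* total time-zero
anisotropy (0.207) exceeds $r_0$; the package keeps the two quantities
separate, uses $r_0$ only in the cone formula, and rejects
$\beta_3 > r_0$ as undefined rather than silently clipping. Reported
angles are rounded to integer degrees.

## EPR: quantitation and power saturation

Spin quantitation is the classical double integral: a cumulative trapezoid
recovers the absorption lineshape from the first-derivative spectrum, a
second trapezoid gives its area, and concentrations follow from the area
ratio to a standard (e.g. 15 µM Cu(II)-EDTA) recorded under identical
non-saturating conditions. An optional linear baseline, fitted to the sweep
edges, can be removed first — quantitation is notoriously
baseline-sensitive.

The synthetic line generator normalizes in closed form so that the double
integral *over the supplied grid*, with the same cumulative-from-the-left
convention the operator uses, equals the requested area. This
grid-referenced normalization is deliberate: a Lorentzian carries several
percent of its area beyond ±10 peak-to-peak linewidths, so an
infinite-support normalization would make equal-area Gaussian and
Lorentzian standards disagree by ~5% on any finite sweep. The generator
warns when the grid covers less than ±5 linewidths.

Power saturation follows $I = C\sqrt{P}\,(1 + P/P_{1/2})^{-b/2}$. The
inhomogeneity exponent $b$ defaults to 1 (the usual choice for Fe-S
centres) and can be fixed elsewhere or fitted. The Levenberg–Marquardt fit
is multi-started from three decades of $P_{1/2}$ guesses around the
geometric mean power; ties resolve to the smallest $P_{1/2}$, making the
result deterministic. Data that never saturate pin $P_{1/2}$ at or beyond
the highest power and are flagged `"upper-bound"`. Nuclearity
classification uses thresholds of 30 and 60 mW: literature [2Fe-2S]⁺
exemplars saturate at ≤10.5 mW and [4Fe-4S]⁺ exemplars at ≥95 mW, so the
thresholds separate the two ranges with a margin band reported as
indeterminate rather than forcing a call.

## Hydrodynamics

All constants are CODATA 2018; standard conditions are water at 20 °C
(η = 0.01002 P, ρ = 0.99823 g/mL — the sednterp convention), and the
svedberg is 10⁻¹³ s. The sedimentation prediction combines the anhydrous
sphere radius with the frictional ratio; the s₂₀,w standardization applies
the viscosity and buoyancy ratios.

The rotational correlation time demands an *explicit* hydration convention
because phrases like "a hydration radius of 40%" are genuinely ambiguous:
read as a volume fraction, as grams of water per gram of protein, or as a
radius scale factor, the same "40%" yields 6.5, 7.1 or 12.7 ns for a
15 kDa protein at 20 °C. Rather than defaulting silently — which would
fabricate precision — `rotationalCorrelation()` requires the convention and
records it in the result's metadata.

## Two-state melts

`fitTwoState()` fits
$s(T) = (1-f_u)\,b_f(T) + f_u\,b_u(T)$ with
$f_u = K/(1+K)$, $K = \exp[-\Delta H/R\,(1/T - 1/T_m)]$ in kelvin
(reported in °C). Baselines (flat or sloped) are profiled out linearly;
the outer optimization runs on $(T_m, \log\Delta H)$, initialized at the
temperature of the maximum smoothed slope — so the derivative-maximum
estimate and the full fit are the initializer and refiner of the same
procedure, and agree on clean two-state data. Melting of real proteins is
often partially irreversible, which formally violates two-state
reversibility; the fitted midpoint should therefore be read as an apparent
$T_m$. Featureless traces (transition amplitude within twice the residual
noise) are flagged non-convergent instead of producing a spurious midpoint.

## The synthetic-data module

The generators emulate exactly the statistical structure the fitters
assume: Poisson counts on reconvolved multi-exponential expectations for
TCSPC (photon counting), multiplicative Gaussian noise for EPR saturation
and additive Gaussian noise for melts (analog detection). The IRF is a
truncated Gaussian — the real IRF of a scattering solution is asymmetric
with an afterpulse tail, but a one-parameter width captures what matters
for reconvolution tests. Defaults encode the study conditions of the Dre2
workflow: literature-scale lifetime/anisotropy models (`dre2Reference()`),
10⁷-count decays, the 0.0002–200 mW power span, 10–80 °C melts at 1 °C
steps, 2% noise for the stochastic recovery checks.

Passing recovery tests on these fixtures demonstrates correctness of the
inference given the model; it does not probe IRF asymmetry, detector
afterpulsing, dead-time pile-up, scattered-light contamination, baseline
drifts beyond linear, or scan-rate-dependent (kinetic) melting hysteresis.
Those effects require real instrument data and are out of scope. Seeds
make every generator bit-reproducible; the full pipeline writes
byte-identical outputs for a fixed config and seed.

Problem sizes in the test suite are chosen to keep a full run on one CPU
within a few minutes: recovery checks run at 1024–4096 channels and
10⁶–10⁷ counts, the MEM $\chi^2$-constraint and oracle-equivalence
properties use 5 seeded datasets, the saturation-bias property 50 seeds,
and the melt-bias property 25 seeds (the bias estimate is already
sub-0.05 °C precise there).

## Pipeline

`runPipeline()` executes stages selected in a single YAML (or list) config
— `tables`, `decay`, `anisotropy`, `epr_saturation`, `epr_quant`, `hydro`,
`melt` — each consuming delimited-text inputs or generating seeded
synthetic data, and writes a machine-readable `results.tsv`, a
`settings.json` sidecar, and a human-readable report. `validateConfig()`
returns typed issues (missing fields, out-of-range values, unknown
enumerations) before anything runs. A stage failure is recorded and the
remaining stages still run. Two bundled configs
(`inst/extdata/tables_demo.yaml`, `full_demo.yaml`) demonstrate the schema;
`inst/scripts/spectrofit.R` is a thin shell wrapper with `run` and
`validate` subcommands.

## Known limitations

* Observed-count Poisson weighting (rather than iteratively reweighted or
  full Poisson likelihood) gives small known biases at finite counts; see
  above.
* The MEM grid is fixed per fit; lifetimes outside the grid bounds alias
  onto the nearest nodes.
* The associative anisotropy model is the only one implemented;
  non-associative schemes are out of scope.
* Hydrodynamic predictions are closed-form sphere models — no bead
  modelling from structures.
* The two-state melt fit knows nothing about irreversibility or scan-rate
  effects.
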