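# SpectroFit

Integrated biophysical characterization of small Fe-S cluster proteins in R,
modelled on the solution workflow used for yeast Dre2: time-resolved
fluorescence (TCSPC) lifetime and anisotropy analysis, EPR spin quantitation
and power saturation, closed-form hydrodynamics, and two-state thermal
unfolding. It is written for spectroscopists and structural biologists who
want the standard analyses of this workflow as tested, scriptable functions,
with a synthetic-data module that generates statistically faithful inputs so
every fitter can be validated end to end without instrument data.

## The models

**Fluorescence decays.** A TCSPC histogram records photon counts per time
channel; the measured decay is the instrument response function (IRF)
convolved with the molecular decay law

> I(t) = Σᵢ αᵢ exp(−t/τᵢ),  Σ αᵢ = 1.

`fitDecay()` fits 1–4 discrete components by iterative reconvolution with
Poisson weighting; `fitMEM()` inverts the same model over a 150-node
logarithmic lifetime grid by maximizing the Skilling–Jaynes entropy
S = Σₖ [aₖ − mₖ − aₖ ln(aₖ/mₖ)] under a χ² constraint, the standard
regularization for this ill-posed inversion. The amplitude-average lifetime
is ⟨τ⟩ = Σ αᵢτᵢ.

**Anisotropy.** Polarized components I_vv(t) ∝ I(t)[1 + 2r(t)]/3 and
I_vh(t) ∝ I(t)[1 − r(t)]/(3G) share the rotational model
r(t) = Σᵢ βᵢ exp(−t/θᵢ) under the associative assumption (every lifetime
carries all rotational correlation times). `fitAnisotropy()` fits both
polarized histograms simultaneously; the wobbling-in-cone semi-angle of the
slow component follows from β₃/r₀ = [½ cos ω (1 + cos ω)]², solved in
closed form by `coneAngle()` (r₀ = 0.185 for tryptophan here).

**EPR.** `spinConcentration()` quantitates S = 1/2 centres by double
integration of the first-derivative spectrum against a standard of known
concentration; `fitSaturation()` fits the microwave power dependence
I = C√P / (1 + P/P_½)^(b/2) and `classifyNuclearity()` reads the Fe-S
nuclearity off P_½ ([2Fe-2S]⁺ saturate at low power, [4Fe-4S]⁺ at high
power).

**Hydrodynamics.** The Svedberg relation
s = M(1 − v̄ρ) / (N_A (f/f₀) 6πη R₀) with the anhydrous sphere radius
R₀ = (3Mv̄ / 4πN_A)^⅓, the s₂₀,w standardization, and the
Stokes–Einstein–Debye rotational correlation time θ = ηV_h / k_BT under an
explicit hydration convention.

**Thermal unfolding.** Two-state van't Hoff melts,
K = exp[−ΔH/R (1/T − 1/T_m)], f_u = K/(1+K), with flat or sloped baselines
(`fitTwoState()`).

## Worked example

Simulate a 10⁷-count decay from the literature three-component lifetime
model of the Dre2 N-terminal domain and refit it:

```r
library(SpectroFit)

ref <- dre2Reference("ntd")
ref$lifetimes
#> DecayComponents ( 3  components )
#>  alpha tau_ns
#>   0.07   0.16
#>   0.13   0.98
#>   0.80   3.18
#>   amplitude-average lifetime: 2.683 ns

irf  <- makeIRF(peakTime = 2, fwhm = 0.5, nChannels = 4096,
                channelWidth = 0.01)
hist <- simulateDecay(ref$lifetimes, irf, totalCounts = 1e7, seed = 1)
fitDecay(hist, nComponents = 3)
#> DecayFit (reduced chi2 = 0.9658  )
#> DecayComponents ( 3  components )
#>   alpha tau_ns
#>  0.0761 0.1158
#>  0.1294 0.9069
#>  0.7945 3.1684
#>   amplitude-average lifetime: 2.643 ns
```

The dominant 3.18 ns lifetime is recovered within counting statistics
(3.168 ns), and the fit's reduced χ² near 1 says the three-exponential
reconvolution model fully explains the simulated data. The derived
quantities behave the same way:

```r
round(coneAngle(0.156, r0 = 0.185), 1)   # wobbling cone of the slow rotor
#> 19.2                                   # degrees: tightly constrained Trp

sedimentationCoefficient(HydroSpec(15000, vbar = 0.753,
                                   frictionalRatio = 1.1))
#> 1.81                                   # svedberg, near-spherical monomer
```

A configuration-driven run of every stage (decay, anisotropy, EPR
saturation and quantitation, hydrodynamics, melt) is bundled:

```r
runPipeline(system.file("extdata", "full_demo.yaml", package = "SpectroFit"),
            outDir = "demo-out")
```

which writes `results.tsv`, `settings.json` and `report.txt`; the run is
byte-reproducible for a fixed config and seed.

## Scope notes

The package covers the forward, closed-form and fitting analyses of the
workflow. It does not implement NMR structure determination, Lamm-equation
c(s) inversion, bead-model hydrodynamics, disorder prediction or
phylogenetics — those belong to the established external tools
(sedfit, hydropro, etc.) used alongside this kind of analysis.
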