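## S4 containers for the measurement objects and fit results.

#' TCSPCHistogram: a channelized photon-count decay with its IRF
#'
#' Container for a time-correlated single photon counting measurement: photon
#' counts per channel, the instrument response function (IRF) measured on the
#' same channel grid, the channel width, and the expected flat background per
#' channel.  The `counts` slot may be empty for an IRF-only object (as
#' returned by [makeIRF()]).
#'
#' @slot channelWidth numeric(1); channel width in ns (> 0).
#' @slot counts numeric; non-negative integer photon counts per channel, or
#'   length zero for an IRF-only histogram.
#' @slot irf numeric; non-negative IRF counts per channel (length >= 64).
#' @slot background numeric(1); expected background counts per channel.
#'
#' @seealso [makeIRF()], [simulateDecay()], [fitDecay()], [fitMEM()]
#' @export
setClass("TCSPCHistogram",
  representation(
    channelWidth = "numeric",
    counts       = "numeric",
    irf          = "numeric",
    background   = "numeric"
  ),
  prototype(channelWidth = 0.01, counts = numeric(), irf = numeric(),
            background = 0)
)

setValidity("TCSPCHistogram", function(object) {
  msg <- character()
  if (length(object@channelWidth) != 1L || !is.finite(object@channelWidth) ||
      object@channelWidth <= 0)
    msg <- c(msg, "channelWidth must be a single positive number (ns)")
  if (length(object@irf) < 64L)
    msg <- c(msg, "irf must have at least 64 channels")
  if (any(object@irf < 0) || any(!is.finite(object@irf)))
    msg <- c(msg, "irf counts must be finite and non-negative")
  if (length(object@counts)) {
    if (length(object@counts) != length(object@irf))
      msg <- c(msg, "counts and irf must share the channel grid")
    if (any(object@counts < 0) || any(!is.finite(object@counts)))
      msg <- c(msg, "counts must be finite and non-negative")
    if (any(abs(object@counts - round(object@counts)) > 1e-8))
      msg <- c(msg, "counts must be integer-valued")
  }
  if (length(object@background) != 1L || object@background < 0)
    msg <- c(msg, "background must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' @describeIn TCSPCHistogram Constructor.
#' @param counts,irf,channelWidth,background see slots.
#' @export
TCSPCHistogram <- function(counts = numeric(), irf, channelWidth,
                           background = 0) {
  new("TCSPCHistogram", channelWidth = as.numeric(channelWidth),
      counts = as.numeric(counts), irf = as.numeric(irf),
      background = as.numeric(background))
}

#' PolarizedDecays: a matched Ivv/Ivh pair of polarized TCSPC decays
#'
#' The vertically (`ivv`) and horizontally (`ivh`) polarized decay components
#' of an anisotropy measurement, sharing the channel grid and IRF, together
#' with the detection-balance G factor.
#'
#' @slot ivv,ivh [TCSPCHistogram-class] objects on an identical grid.
#' @slot gFactor numeric(1); detection-balance ratio (> 0).
#' @seealso [simulatePolarized()], [anisotropyCurve()], [fitAnisotropy()]
#' @export
setClass("PolarizedDecays",
  representation(ivv = "TCSPCHistogram", ivh = "TCSPCHistogram",
                 gFactor = "numeric"),
  prototype(gFactor = 1)
)

setValidity("PolarizedDecays", function(object) {
  msg <- character()
  if (length(object@gFactor) != 1L || !is.finite(object@gFactor) ||
      object@gFactor <= 0)
    msg <- c(msg, "gFactor must be a single positive number")
  if (length(object@ivv@irf) != length(object@ivh@irf) ||
      object@ivv@channelWidth != object@ivh@channelWidth)
    msg <- c(msg, "ivv and ivh must share the channel grid")
  else if (any(object@ivv@irf != object@ivh@irf))
    msg <- c(msg, "ivv and ivh must share the IRF")
  if (length(msg)) msg else TRUE
})

#' @describeIn PolarizedDecays Constructor.
#' @param ivv,ivh,gFactor see slots.
#' @export
PolarizedDecays <- function(ivv, ivh, gFactor = 1) {
  new("PolarizedDecays", ivv = ivv, ivh = ivh, gFactor = as.numeric(gFactor))
}

#' DecayComponents: a discrete multi-exponential intensity model
#'
#' Normalized amplitudes and excited-state lifetimes of the intensity decay
#' model I(t) = sum_i alpha_i exp(-t / tau_i).  Components are stored sorted
#' by ascending lifetime.
#'
#' @slot amplitudes numeric; normalized amplitudes alpha_i (>= 0, sum to 1).
#' @slot lifetimes numeric; lifetimes tau_i in ns (> 0, ascending).
#' @seealso [amplitudeAverageLifetime()], [fitDecay()], [simulateDecay()]
#' @export
setClass("DecayComponents",
  representation(amplitudes = "numeric", lifetimes = "numeric")
)

setValidity("DecayComponents", function(object) {
  msg <- character()
  if (length(object@amplitudes) != length(object@lifetimes))
    msg <- c(msg, "amplitudes and lifetimes must have equal length")
  if (!length(object@amplitudes))
    msg <- c(msg, "at least one component is required")
  if (any(object@amplitudes < 0))
    msg <- c(msg, "amplitudes must be non-negative")
  if (any(object@lifetimes <= 0))
    msg <- c(msg, "lifetimes must be positive")
  if (length(object@amplitudes) &&
      abs(sum(object@amplitudes) - 1) > 1e-6)
    msg <- c(msg, "amplitudes must sum to 1 (use normalize = TRUE)")
  if (is.unsorted(object@lifetimes))
    msg <- c(msg, "lifetimes must be sorted ascending")
  if (length(msg)) msg else TRUE
})

#' @describeIn DecayComponents Constructor; sorts by lifetime and optionally
#'   normalizes the amplitudes to unit sum.
#' @param amplitudes,lifetimes see slots.
#' @param normalize logical; rescale amplitudes to sum to 1.
#' @export
DecayComponents <- function(amplitudes, lifetimes, normalize = FALSE) {
  o <- order(lifetimes)
  a <- as.numeric(amplitudes)[o]
  if (normalize && sum(a) > 0) a <- a / sum(a)
  new("DecayComponents", amplitudes = a, lifetimes = as.numeric(lifetimes)[o])
}

#' AnisotropyComponents: a discrete rotational-correlation model
#'
#' Amplitudes and rotational correlation times of the anisotropy decay
#' r(t) = sum_i beta_i exp(-t / theta_i), plus the fundamental anisotropy r0
#' used by the wobbling-in-cone analysis.  The total time-zero anisotropy
#' r(t=0) equals sum(beta_i) and is available through [rTotal()].
#'
#' @slot betas numeric; anisotropy amplitudes beta_i (>= 0).
#' @slot thetas numeric; rotational correlation times theta_i in ns
#'   (> 0, ascending).
#' @slot r0 numeric(1); fundamental anisotropy (default 0.185, the value for
#'   tryptophan at the excitation wavelength used here).
#' @seealso [coneAngle()], [fitAnisotropy()], [simulatePolarized()]
#' @export
setClass("AnisotropyComponents",
  representation(betas = "numeric", thetas = "numeric", r0 = "numeric"),
  prototype(r0 = 0.185)
)

setValidity("AnisotropyComponents", function(object) {
  msg <- character()
  if (length(object@betas) != length(object@thetas))
    msg <- c(msg, "betas and thetas must have equal length")
  if (any(object@betas < 0))
    msg <- c(msg, "betas must be non-negative")
  if (any(object@thetas <= 0))
    msg <- c(msg, "thetas must be positive")
  if (sum(object@betas) > 0.4 + 1e-9)
    msg <- c(msg, "total time-zero anisotropy sum(betas) must not exceed 0.4")
  if (is.unsorted(object@thetas))
    msg <- c(msg, "thetas must be sorted ascending")
  if (length(object@r0) != 1L || object@r0 <= 0 || object@r0 > 0.4)
    msg <- c(msg, "r0 must be a single value in (0, 0.4]")
  if (length(msg)) msg else TRUE
})

#' @describeIn AnisotropyComponents Constructor; sorts by correlation time.
#' @param betas,thetas,r0 see slots.
#' @export
AnisotropyComponents <- function(betas, thetas, r0 = 0.185) {
  o <- order(thetas)
  new("AnisotropyComponents", betas = as.numeric(betas)[o],
      thetas = as.numeric(thetas)[o], r0 = as.numeric(r0))
}

#' LifetimeDistribution: a maximum-entropy lifetime amplitude density
#'
#' Result of [fitMEM()]: non-negative amplitude weights on a logarithmic
#' lifetime grid, with the reduced chi-squared of the reconvolved mixture and
#' the solver status.
#'
#' @slot tauGrid numeric; strictly increasing lifetime grid (ns).
#' @slot density numeric; non-negative amplitude weight per node (photon
#'   counts at the data scale).
#' @slot chi2Reduced numeric(1); reduced chi-squared of the solution.
#' @slot status character(1); one of `"converged"`, `"prior"` (the prior
#'   already satisfies the chi-squared constraint) or `"infeasible"` (the
#'   constraint could not be reached; best-chi2 solution returned).
#' @seealso [fitMEM()], [extractComponents()]
#' @export
setClass("LifetimeDistribution",
  representation(tauGrid = "numeric", density = "numeric",
                 chi2Reduced = "numeric", status = "character"),
  prototype(status = "converged")
)

setValidity("LifetimeDistribution", function(object) {
  msg <- character()
  if (length(object@tauGrid) != length(object@density))
    msg <- c(msg, "tauGrid and density must have equal length")
  if (any(diff(object@tauGrid) <= 0))
    msg <- c(msg, "tauGrid must be strictly increasing")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative")
  if (!object@status %in% c("converged", "prior", "infeasible"))
    msg <- c(msg, "status must be converged, prior or infeasible")
  if (length(msg)) msg else TRUE
})

#' MEMSettings: settings for the maximum-entropy solver
#'
#' @slot prior numeric; prior weights m_k on the lifetime grid, or length
#'   zero for the default flat prior scaled to the observed counts.
#' @slot chi2Target numeric(1); target chi-squared of the constraint.  `NA`
#'   (default) means the number of fitted channels, i.e. reduced chi-squared
#'   of 1.
#' @slot maxIterations numeric(1); maximum inner-solver iterations.
#' @slot tol numeric(1); relative tolerance on |chi2 - target| / target.
#' @slot gradTol numeric(1); projected-gradient tolerance of the inner solver.
#' @seealso [fitMEM()]
#' @export
setClass("MEMSettings",
  representation(prior = "numeric", chi2Target = "numeric",
                 maxIterations = "numeric", tol = "numeric",
                 gradTol = "numeric"),
  prototype(prior = numeric(), chi2Target = NA_real_, maxIterations = 2000,
            tol = 1e-3, gradTol = 1e-6)
)

setValidity("MEMSettings", function(object) {
  msg <- character()
  if (!is.na(object@chi2Target) && object@chi2Target <= 0)
    msg <- c(msg, "chi2Target must be positive")
  if (any(object@prior < 0))
    msg <- c(msg, "prior weights must be non-negative")
  if (object@tol <= 0 || object@gradTol <= 0 || object@maxIterations < 1)
    msg <- c(msg, "tolerances must be positive and maxIterations >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn MEMSettings Constructor.
#' @param prior,chi2Target,maxIterations,tol,gradTol see slots.
#' @export
MEMSettings <- function(prior = numeric(), chi2Target = NA_real_,
                        maxIterations = 2000, tol = 1e-3, gradTol = 1e-6) {
  new("MEMSettings", prior = as.numeric(prior),
      chi2Target = as.numeric(chi2Target),
      maxIterations = as.numeric(maxIterations), tol = as.numeric(tol),
      gradTol = as.numeric(gradTol))
}

#' DecayFit: result of a discrete multi-exponential reconvolution fit
#'
#' @slot components [DecayComponents-class]; the fitted model.
#' @slot chi2Reduced numeric(1); reduced chi-squared.
#' @slot scale numeric(1); total model amplitude in counts.
#' @slot shift numeric(1); sub-channel IRF shift used (channels).
#' @slot converged logical(1); `FALSE` flags non-convergence or a degenerate
#'   solution (merged lifetimes / near-zero amplitude).
#' @slot fitRange numeric(2); first and last fitted channel.
#' @seealso [fitDecay()]
#' @export
setClass("DecayFit",
  representation(components = "DecayComponents", chi2Reduced = "numeric",
                 scale = "numeric", shift = "numeric", converged = "logical",
                 fitRange = "numeric")
)

#' AnisotropyFit: result of an associative-model polarized fit
#'
#' @slot components [AnisotropyComponents-class]; the fitted rotational model.
#' @slot chi2Reduced numeric(1); reduced chi-squared over both polarized
#'   components.
#' @slot scale numeric(1); total intensity amplitude in counts.
#' @slot converged logical(1); `FALSE` flags non-convergence or degeneracy.
#' @seealso [fitAnisotropy()]
#' @export
setClass("AnisotropyFit",
  representation(components = "AnisotropyComponents", chi2Reduced = "numeric",
                 scale = "numeric", converged = "logical")
)

#' EPRSpectrum: a field-swept first-derivative EPR spectrum
#'
#' @slot field numeric; uniform, strictly increasing magnetic-field grid (mT).
#' @slot intensity numeric; first-derivative signal (arbitrary units).
#' @slot frequency numeric(1); microwave frequency (GHz).
#' @seealso [simulateEPRLine()], [doubleIntegral()], [differenceSpectrum()]
#' @export
setClass("EPRSpectrum",
  representation(field = "numeric", intensity = "numeric",
                 frequency = "numeric")
)

setValidity("EPRSpectrum", function(object) {
  msg <- character()
  if (length(object@field) < 32L)
    msg <- c(msg, "field grid must have at least 32 points")
  if (length(object@field) != length(object@intensity))
    msg <- c(msg, "field and intensity must have equal length")
  d <- diff(object@field)
  if (any(d <= 0))
    msg <- c(msg, "field grid must be strictly increasing")
  else if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
    msg <- c(msg, "field grid must be uniform (1e-6 relative)")
  if (length(object@frequency) != 1L || object@frequency <= 0)
    msg <- c(msg, "frequency must be a single positive number (GHz)")
  if (length(msg)) msg else TRUE
})

#' @describeIn EPRSpectrum Constructor.
#' @param field,intensity,frequency see slots.
#' @export
EPRSpectrum <- function(field, intensity, frequency) {
  new("EPRSpectrum", field = as.numeric(field),
      intensity = as.numeric(intensity), frequency = as.numeric(frequency))
}

#' SaturationSeries: an EPR microwave power-saturation series
#'
#' @slot powers numeric; microwave powers (mW, > 0).
#' @slot intensities numeric; signal intensities (arbitrary units).
#' @seealso [simulateSaturation()], [fitSaturation()]
#' @export
setClass("SaturationSeries",
  representation(powers = "numeric", intensities = "numeric")
)

setValidity("SaturationSeries", function(object) {
  msg <- character()
  if (!length(object@powers))
    msg <- c(msg, "powers must be non-empty")
  if (length(object@powers) != length(object@intensities))
    msg <- c(msg, "powers and intensities must have equal length")
  if (any(object@powers <= 0))
    msg <- c(msg, "powers must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SaturationSeries Constructor.
#' @param powers,intensities see slots.
#' @export
SaturationSeries <- function(powers, intensities) {
  new("SaturationSeries", powers = as.numeric(powers),
      intensities = as.numeric(intensities))
}

#' SaturationFit: result of a power-saturation fit
#'
#' @slot pHalf numeric(1); microwave power at half saturation (mW).
#' @slot scaleC numeric(1); scaling factor C.
#' @slot b numeric(1); inhomogeneity exponent.
#' @slot residualNorm numeric(1); residual sum of squares.
#' @slot status character(1); `"ok"` or `"upper-bound"` for monotone
#'   non-saturating data (P1/2 pinned at or beyond the highest power).
#' @seealso [fitSaturation()]
#' @export
setClass("SaturationFit",
  representation(pHalf = "numeric", scaleC = "numeric", b = "numeric",
                 residualNorm = "numeric", status = "character"),
  prototype(status = "ok")
)

setValidity("SaturationFit", function(object) {
  if (object@pHalf <= 0) "pHalf must be positive" else TRUE
})

#' HydroSpec: inputs for closed-form hydrodynamic predictions
#'
#' @slot mass numeric(1); molar mass (Da).
#' @slot vbar numeric(1); partial specific volume (mL/g).
#' @slot viscosity numeric(1); solvent viscosity (poise).
#' @slot density numeric(1); solvent density (g/mL).
#' @slot temperature numeric(1); absolute temperature (K).
#' @slot frictionalRatio numeric(1); f/f0 (>= 1).
#' @slot hydration numeric(1); hydration parameter whose meaning is set by
#'   the convention argument of [rotationalCorrelation()].
#' @seealso [sedimentationCoefficient()], [rotationalCorrelation()]
#' @export
setClass("HydroSpec",
  representation(mass = "numeric", vbar = "numeric", viscosity = "numeric",
                 density = "numeric", temperature = "numeric",
                 frictionalRatio = "numeric", hydration = "numeric"),
  prototype(vbar = 0.753, viscosity = 0.01002, density = 0.99823,
            temperature = 293.15, frictionalRatio = 1, hydration = 0)
)

setValidity("HydroSpec", function(object) {
  msg <- character()
  sl <- c(mass = object@mass, vbar = object@vbar,
          viscosity = object@viscosity, density = object@density,
          temperature = object@temperature)
  bad <- names(sl)[!is.finite(sl) | sl <= 0]
  if (length(bad))
    msg <- c(msg, paste0(paste(bad, collapse = ", "), " must be positive"))
  if (object@frictionalRatio < 1)
    msg <- c(msg, "frictionalRatio must be >= 1")
  if (object@hydration < 0)
    msg <- c(msg, "hydration must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn HydroSpec Constructor.  Defaults describe water at 20 C.
#' @param mass,vbar,viscosity,density,temperature,frictionalRatio,hydration
#'   see slots.
#' @export
HydroSpec <- function(mass, vbar = 0.753, viscosity = 0.01002,
                      density = 0.99823, temperature = 293.15,
                      frictionalRatio = 1, hydration = 0) {
  new("HydroSpec", mass = as.numeric(mass), vbar = as.numeric(vbar),
      viscosity = as.numeric(viscosity), density = as.numeric(density),
      temperature = as.numeric(temperature),
      frictionalRatio = as.numeric(frictionalRatio),
      hydration = as.numeric(hydration))
}

#' MeltCurve: a thermal denaturation trace
#'
#' Temperature/signal pairs of a melting experiment (for example CD
#' ellipticity followed against temperature).  The constructor sorts by
#' temperature so that traces recorded in either direction are equivalent.
#'
#' @slot temperature numeric; strictly increasing temperatures (deg C, >= 10
#'   points).
#' @slot signal numeric; observed signal (arbitrary units).
#' @seealso [simulateMelt()], [fitTwoState()]
#' @export
setClass("MeltCurve",
  representation(temperature = "numeric", signal = "numeric")
)

setValidity("MeltCurve", function(object) {
  msg <- character()
  if (length(object@temperature) < 10L)
    msg <- c(msg, "at least 10 temperature points are required")
  if (length(object@temperature) != length(object@signal))
    msg <- c(msg, "temperature and signal must have equal length")
  if (any(diff(object@temperature) <= 0))
    msg <- c(msg, "temperatures must be strictly increasing (duplicates not allowed)")
  if (length(msg)) msg else TRUE
})

#' @describeIn MeltCurve Constructor; sorts by temperature.
#' @param temperature,signal see slots.
#' @export
MeltCurve <- function(temperature, signal) {
  o <- order(temperature)
  new("MeltCurve", temperature = as.numeric(temperature)[o],
      signal = as.numeric(signal)[o])
}

#' TwoStateFit: result of a two-state van't Hoff melt fit
#'
#' @slot tm numeric(1); apparent melting midpoint (deg C).
#' @slot dH numeric(1); van't Hoff enthalpy (kJ/mol).
#' @slot baselineFolded numeric(2); intercept and slope of the folded
#'   baseline (signal units, per deg C).
#' @slot baselineUnfolded numeric(2); intercept and slope of the unfolded
#'   baseline.
#' @slot residualSd numeric(1); residual standard deviation.
#' @slot converged logical(1); `FALSE` flags featureless or non-convergent
#'   data.
#' @seealso [fitTwoState()]
#' @export
setClass("TwoStateFit",
  representation(tm = "numeric", dH = "numeric", baselineFolded = "numeric",
                 baselineUnfolded = "numeric", residualSd = "numeric",
                 converged = "logical")
)
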