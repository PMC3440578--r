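## Accessor methods and show() methods.

#' Accessors for SpectroFit containers
#'
#' Slot accessors for the S4 measurement and result classes; use these rather
#' than `@`.  `timeAxis()` returns channel-midpoint times in ns; `rTotal()`
#' returns the time-zero anisotropy sum(betas); `densityWeights()` the MEM
#' amplitude density; `fitStatus()` the solver status string.
#'
#' @param object one of the SpectroFit S4 objects.
#' @return The corresponding slot value (numeric or character).
#' @name accessors
NULL

#' @rdname accessors
setMethod("channelWidth", "TCSPCHistogram", function(object) object@channelWidth)
#' @rdname accessors
setMethod("decayCounts", "TCSPCHistogram", function(object) object@counts)
#' @rdname accessors
setMethod("irfCounts", "TCSPCHistogram", function(object) object@irf)
#' @rdname accessors
setMethod("background", "TCSPCHistogram", function(object) object@background)
#' @rdname accessors
setMethod("timeAxis", "TCSPCHistogram", function(object)
  (seq_along(object@irf) - 0.5) * object@channelWidth)

#' @rdname accessors
setMethod("gFactor", "PolarizedDecays", function(object) object@gFactor)
#' @rdname accessors
setMethod("timeAxis", "PolarizedDecays", function(object) timeAxis(object@ivv))

#' @rdname accessors
setMethod("amplitudes", "DecayComponents", function(object) object@amplitudes)
#' @rdname accessors
setMethod("lifetimes", "DecayComponents", function(object) object@lifetimes)

#' @rdname accessors
setMethod("betas", "AnisotropyComponents", function(object) object@betas)
#' @rdname accessors
setMethod("thetas", "AnisotropyComponents", function(object) object@thetas)
#' @rdname accessors
setMethod("r0", "AnisotropyComponents", function(object) object@r0)
#' @rdname accessors
setMethod("rTotal", "AnisotropyComponents", function(object) sum(object@betas))

#' @rdname accessors
setMethod("tauGrid", "LifetimeDistribution", function(object) object@tauGrid)
#' @rdname accessors
setMethod("densityWeights", "LifetimeDistribution",
          function(object) object@density)
#' @rdname accessors
setMethod("chi2Reduced", "LifetimeDistribution",
          function(object) object@chi2Reduced)
#' @rdname accessors
setMethod("fitStatus", "LifetimeDistribution", function(object) object@status)

#' @rdname accessors
setMethod("components", "DecayFit", function(object) object@components)
#' @rdname accessors
setMethod("chi2Reduced", "DecayFit", function(object) object@chi2Reduced)
#' @rdname accessors
setMethod("amplitudes", "DecayFit", function(object) object@components@amplitudes)
#' @rdname accessors
setMethod("lifetimes", "DecayFit", function(object) object@components@lifetimes)

#' @rdname accessors
setMethod("components", "AnisotropyFit", function(object) object@components)
#' @rdname accessors
setMethod("chi2Reduced", "AnisotropyFit", function(object) object@chi2Reduced)
#' @rdname accessors
setMethod("betas", "AnisotropyFit", function(object) object@components@betas)
#' @rdname accessors
setMethod("thetas", "AnisotropyFit", function(object) object@components@thetas)
#' @rdname accessors
setMethod("rTotal", "AnisotropyFit",
          function(object) sum(object@components@betas))

#' @rdname accessors
setMethod("fieldAxis", "EPRSpectrum", function(object) object@field)
#' @rdname accessors
setMethod("intensities", "EPRSpectrum", function(object) object@intensity)
#' @rdname accessors
setMethod("frequencyGHz", "EPRSpectrum", function(object) object@frequency)

#' @rdname accessors
setMethod("powers", "SaturationSeries", function(object) object@powers)
#' @rdname accessors
setMethod("intensities", "SaturationSeries",
          function(object) object@intensities)

#' @rdname accessors
setMethod("pHalf", "SaturationFit", function(object) object@pHalf)
#' @rdname accessors
setMethod("fitStatus", "SaturationFit", function(object) object@status)

#' @rdname accessors
setMethod("meltingPoint", "TwoStateFit", function(object) object@tm)
#' @rdname accessors
setMethod("vantHoffEnthalpy", "TwoStateFit", function(object) object@dH)

## show methods ---------------------------------------------------------------

setMethod("show", "TCSPCHistogram", function(object) {
  n <- length(object@irf)
  cat("TCSPCHistogram:", n, "channels x", object@channelWidth, "ns",
      sprintf("(window %.2f ns)\n", n * object@channelWidth))
  if (length(object@counts))
    cat("  counts:", format(sum(object@counts), big.mark = ","),
        "photons; background", format(object@background), "per channel\n")
  else
    cat("  IRF-only (counts slot empty)\n")
  cat("  IRF total:", format(round(sum(object@irf)), big.mark = ","),
      "; peak at channel", which.max(object@irf), "\n")
})

setMethod("show", "PolarizedDecays", function(object) {
  cat("PolarizedDecays (G =", object@gFactor, ")\n")
  cat("  Ivv:", format(sum(object@ivv@counts), big.mark = ","),
      "counts; Ivh:", format(sum(object@ivh@counts), big.mark = ","),
      "counts over", length(object@ivv@irf), "channels\n")
})

setMethod("show", "DecayComponents", function(object) {
  cat("DecayComponents (", length(object@lifetimes), " components )\n")
  print(data.frame(alpha = round(object@amplitudes, 4),
                   tau_ns = round(object@lifetimes, 4)), row.names = FALSE)
  cat("  amplitude-average lifetime:",
      round(sum(object@amplitudes * object@lifetimes), 3), "ns\n")
})

setMethod("show", "AnisotropyComponents", function(object) {
  cat("AnisotropyComponents (", length(object@thetas), " rotors, r0 =",
      object@r0, ")\n")
  print(data.frame(beta = round(object@betas, 4),
                   theta_ns = round(object@thetas, 3)), row.names = FALSE)
  cat("  r(t=0) =", round(sum(object@betas), 4), "\n")
})

setMethod("show", "LifetimeDistribution", function(object) {
  cat("LifetimeDistribution:", length(object@tauGrid), "nodes over [",
      round(min(object@tauGrid), 4), ",", round(max(object@tauGrid), 2),
      "] ns\n")
  cat("  reduced chi2:", round(object@chi2Reduced, 4), "; status:",
      object@status, "\n")
})

setMethod("show", "DecayFit", function(object) {
  cat("DecayFit (reduced chi2 =", round(object@chi2Reduced, 4),
      if (!object@converged) ", FLAGGED" else "", ")\n")
  show(object@components)
})

setMethod("show", "AnisotropyFit", function(object) {
  cat("AnisotropyFit (reduced chi2 =", round(object@chi2Reduced, 4),
      if (!object@converged) ", FLAGGED" else "", ")\n")
  show(object@components)
})

setMethod("show", "EPRSpectrum", function(object) {
  cat("EPRSpectrum:", length(object@field), "points,",
      round(min(object@field), 2), "-", round(max(object@field), 2),
      "mT at", object@frequency, "GHz\n")
})

setMethod("show", "SaturationSeries", function(object) {
  cat("SaturationSeries:", length(object@powers), "powers,",
      format(min(object@powers)), "-", format(max(object@powers)), "mW\n")
})

setMethod("show", "SaturationFit", function(object) {
  cat("SaturationFit: P1/2 =", signif(object@pHalf, 4), "mW; C =",
      signif(object@scaleC, 4), "; b =", signif(object@b, 4),
      "; status:", object@status, "\n")
})

setMethod("show", "HydroSpec", function(object) {
  cat("HydroSpec:", object@mass, "Da, vbar", object@vbar, "mL/g, eta",
      object@viscosity, "P, rho", object@density, "g/mL, T",
      object@temperature, "K, f/f0", object@frictionalRatio,
      ", hydration", object@hydration, "\n")
})

setMethod("show", "MeltCurve", function(object) {
  cat("MeltCurve:", length(object@temperature), "points,",
      min(object@temperature), "-", max(object@temperature), "deg C\n")
})

setMethod("show", "TwoStateFit", function(object) {
  cat("TwoStateFit: Tm =", round(object@tm, 2), "deg C; dH(vH) =",
      round(object@dH, 1), "kJ/mol",
      if (!object@converged) "(FLAGGED non-convergent)" else "", "\n")
})
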