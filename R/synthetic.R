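## Synthetic-data generators.  Every forward model here is exactly the model
## its paired fitter assumes, so noiseless generator output is recovered
## exactly and noisy recovery is a statistically calibrated oracle.

.checkSeed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer")
  as.integer(seed)
}

#' Generate a truncated-Gaussian instrument response function
#'
#' The IRF of a TCSPC instrument is measured with a scattering solution; here
#' it is modelled as a Gaussian pulse truncated to the time window, discretized
#' at channel midpoints.  The limit `fwhm -> 0` concentrates all mass in the
#' channel containing `peakTime`.
#'
#' @param peakTime pulse peak position (ns); must lie inside the time window.
#' @param fwhm full width at half maximum of the pulse (ns, > 0).
#' @param nChannels number of channels (default 4096).
#' @param channelWidth channel width (ns, default 0.01).
#' @param totalCounts total IRF counts (default 1e6).
#' @return A [TCSPCHistogram-class] with an empty `counts` slot.
#' @examples
#' irf <- makeIRF(2, 0.5)
#' sum(irfCounts(irf))
#' @export
makeIRF <- function(peakTime, fwhm, nChannels = 4096, channelWidth = 0.01,
                    totalCounts = 1e6) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  if (nChannels < 64 || channelWidth <= 0)
    stop("need at least 64 channels of positive width")
  window <- nChannels * channelWidth
  if (peakTime <= 0 || peakTime >= window)
    stop("peakTime must lie inside the time window (0, ",
         format(window), ") ns")
  t <- (seq_len(nChannels) - 0.5) * channelWidth
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  dens <- exp(-0.5 * ((t - peakTime) / sigma)^2)
  if (sum(dens) == 0) { # fwhm far below channel width: delta limit
    dens <- numeric(nChannels)
    dens[which.min(abs(t - peakTime))] <- 1
  }
  irf <- round(totalCounts * dens / sum(dens))
  TCSPCHistogram(irf = irf, channelWidth = channelWidth)
}

#' Simulate a Poisson-noised TCSPC intensity decay
#'
#' Expected counts are the discrete convolution of the normalized IRF with
#' the multi-exponential model plus a flat background, rescaled so the total
#' expectation equals `totalCounts`, then Poisson-sampled.  Identical
#' arguments and seed give bit-identical output.
#'
#' @param components normalized [DecayComponents-class].
#' @param irf a [TCSPCHistogram-class] carrying the IRF and grid.
#' @param totalCounts expected total photon count (>= 1e4).
#' @param backgroundFraction fraction of `totalCounts` distributed as a flat
#'   background (default 0).
#' @param seed integer RNG seed.
#' @return A [TCSPCHistogram-class] with Poisson-sampled counts and the
#'   background expectation recorded.
#' @examples
#' irf <- makeIRF(2, 0.5, nChannels = 1024, channelWidth = 0.02)
#' hist <- simulateDecay(DecayComponents(1, 2), irf, 1e5, seed = 1)
#' @export
simulateDecay <- function(components, irf, totalCounts,
                          backgroundFraction = 0, seed) {
  stopifnot(is(components, "DecayComponents"), is(irf, "TCSPCHistogram"))
  if (abs(sum(components@amplitudes) - 1) > 1e-6)
    stop("component amplitudes must be normalized to unit sum")
  if (totalCounts < 1e4)
    stop("totalCounts must be at least 1e4 for meaningful statistics")
  if (backgroundFraction < 0 || backgroundFraction >= 1)
    stop("backgroundFraction must be in [0, 1)")
  seed <- .checkSeed(seed)
  n <- length(irf@irf)
  p <- .irfProfile(irf@irf)
  B <- .expBasis(components@lifetimes, n, irf@channelWidth)
  conv <- .convolveIRF(p, as.vector(B %*% components@amplitudes))
  signal <- totalCounts * (1 - backgroundFraction)
  bg <- backgroundFraction * totalCounts / n
  expected <- signal * conv / sum(conv) + bg
  set.seed(seed)
  TCSPCHistogram(counts = stats::rpois(n, expected), irf = irf@irf,
                 channelWidth = irf@channelWidth, background = bg)
}

#' Simulate polarized TCSPC decays under the associative model
#'
#' Expected polarized components are Ivv(t) proportional to I(t)(1 + 2 r(t))/3
#' and Ivh(t) proportional to I(t)(1 - r(t))/(3 G), each convolved with the
#' IRF, where every lifetime is associated with all rotational correlation
#' times (associative model) so that r(t) = sum(beta_i exp(-t/theta_i))
#' multiplies the total intensity decay.  One shared scale is chosen so the
#' combined expected counts equal `2 * totalCounts` (an average budget of
#' `totalCounts` per detector), preserving the vv/vh ratio that encodes r(t).
#'
#' @param components intensity [DecayComponents-class].
#' @param aniso [AnisotropyComponents-class]; total time-zero anisotropy must
#'   not exceed 0.4 and r(t) must stay within [-0.2, 0.4].
#' @param irf a [TCSPCHistogram-class] carrying the IRF and grid.
#' @param gFactor detection-balance ratio (default 1).
#' @param totalCounts average expected photon count per detector.
#' @param backgroundFraction flat background fraction per detector.
#' @param seed integer RNG seed.
#' @return A [PolarizedDecays-class] object.
#' @export
simulatePolarized <- function(components, aniso, irf, gFactor = 1,
                              totalCounts, backgroundFraction = 0, seed) {
  stopifnot(is(components, "DecayComponents"),
            is(aniso, "AnisotropyComponents"), is(irf, "TCSPCHistogram"))
  if (sum(aniso@betas) > 0.4 + 1e-9)
    stop("total time-zero anisotropy must not exceed 0.4")
  if (gFactor <= 0) stop("gFactor must be positive")
  seed <- .checkSeed(seed)
  n <- length(irf@irf)
  t <- (seq_len(n) - 0.5) * irf@channelWidth
  Bi <- .expBasis(components@lifetimes, n, irf@channelWidth)
  I <- as.vector(Bi %*% components@amplitudes)
  r <- as.vector(.expBasis(aniso@thetas, n, irf@channelWidth) %*% aniso@betas)
  if (any(r < -0.2 - 1e-9) || any(r > 0.4 + 1e-9))
    stop("r(t) leaves the physical range [-0.2, 0.4]")
  p <- .irfProfile(irf@irf)
  mvv <- .convolveIRF(p, I * (1 + 2 * r) / 3)
  mvh <- .convolveIRF(p, I * (1 - r) / (3 * gFactor))
  scale <- 2 * totalCounts * (1 - backgroundFraction) / (sum(mvv) + sum(mvh))
  bg <- backgroundFraction * totalCounts / n
  set.seed(seed)
  cvv <- stats::rpois(n, scale * mvv + bg)
  cvh <- stats::rpois(n, scale * mvh + bg)
  PolarizedDecays(
    ivv = TCSPCHistogram(cvv, irf@irf, irf@channelWidth, bg),
    ivh = TCSPCHistogram(cvh, irf@irf, irf@channelWidth, bg),
    gFactor = gFactor)
}

#' Simulate an EPR power-saturation series
#'
#' Intensity follows the standard saturation law
#' `I = C * sqrt(P) / (1 + P / P1/2)^(b/2)` with multiplicative Gaussian
#' noise.
#'
#' @param scaleC scaling factor C.
#' @param pHalf microwave power at half saturation (mW, > 0).
#' @param b inhomogeneity exponent (default 1).
#' @param powers vector of microwave powers (mW, > 0, non-empty).
#' @param noiseFraction standard deviation of the multiplicative noise
#'   (default 0).
#' @param seed integer RNG seed (only used when `noiseFraction > 0`).
#' @return A [SaturationSeries-class].
#' @examples
#' s <- simulateSaturation(1, 2.5, powers = 10^seq(-3.7, 2.3, 0.3),
#'                         noiseFraction = 0.02, seed = 3)
#' @export
simulateSaturation <- function(scaleC, pHalf, b = 1, powers,
                               noiseFraction = 0, seed = 1) {
  if (!length(powers)) stop("powers must be non-empty")
  if (any(powers <= 0)) stop("powers must be positive")
  if (pHalf <= 0) stop("pHalf must be positive")
  ideal <- scaleC * sqrt(powers) / (1 + powers / pHalf)^(b / 2)
  if (noiseFraction > 0) {
    set.seed(.checkSeed(seed))
    ideal <- ideal * (1 + stats::rnorm(length(ideal), sd = noiseFraction))
  }
  SaturationSeries(powers, ideal)
}

#' Simulate a first-derivative EPR line of known double integral
#'
#' Returns the first derivative of a Gaussian or Lorentzian absorption line
#' whose double integral over the supplied field grid equals `area` in the
#' continuum limit.  The normalization is closed-form and grid-referenced:
#' the second integral of the cumulative first integral, i.e. exactly the
#' quantity [doubleIntegral()] computes, so finite-window truncation of the
#' Lorentzian tails does not bias quantitation against a Gaussian standard.
#'
#' @param centerField line center (mT).
#' @param linewidth peak-to-peak width of the derivative line (mT, > 0).
#' @param area requested double-integral area.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param frequency microwave frequency (GHz).
#' @param fieldGrid uniform increasing field grid (mT).  A grid narrower than
#'   +/- 5 linewidths around the center triggers a truncation-bias warning.
#' @return An [EPRSpectrum-class].
#' @export
simulateEPRLine <- function(centerField, linewidth, area = 1,
                            shape = c("gaussian", "lorentzian"),
                            frequency = 9.44342, fieldGrid) {
  shape <- match.arg(shape)
  if (linewidth <= 0) stop("linewidth must be positive")
  if (min(fieldGrid) > centerField - 5 * linewidth ||
      max(fieldGrid) < centerField + 5 * linewidth)
    warning("field grid covers less than +/- 5 linewidths: ",
            "double-integral truncation bias likely")
  x <- fieldGrid - centerField
  a <- min(x); bb <- max(x)
  if (shape == "gaussian") {
    sigma <- linewidth / 2            # derivative extrema at +/- sigma
    f  <- function(x) exp(-0.5 * (x / sigma)^2) / (sigma * sqrt(2 * pi))
    Fc <- function(x) stats::pnorm(x, sd = sigma)
    deriv <- -x / sigma^2 * f(x)
  } else {
    gam <- sqrt(3) / 2 * linewidth    # derivative extrema at +/- gamma/sqrt(3)
    f  <- function(x) (gam / pi) / (x^2 + gam^2)
    Fc <- function(x) 0.5 + atan(x / gam) / pi
    deriv <- -2 * x * gam / (pi * (x^2 + gam^2)^2)
  }
  # Analytic double integral of the unit line over [a, b] with the
  # cumulative-from-the-left convention: int_a^b [f(B) - f(a)] dB.
  D <- (Fc(bb) - Fc(a)) - (bb - a) * f(a)
  if (D <= 0) stop("field grid does not support the requested line")
  EPRSpectrum(fieldGrid, (area / D) * deriv, frequency)
}

#' Simulate a two-state thermal denaturation curve
#'
#' Signal is the population-weighted mixture of linear folded and unfolded
#' baselines, `signal(T) = (1 - fu) basef(T) + fu baseu(T)`, with the
#' unfolded fraction given by the van't Hoff two-state model
#' `K = exp(-dH/R (1/T - 1/Tm))` in kelvin and `fu = K / (1 + K)`, plus
#' additive Gaussian noise.
#'
#' @param midpoint melting midpoint Tm (deg C); must lie inside `temps`.
#' @param dH van't Hoff enthalpy (kJ/mol, > 0).
#' @param foldedBaseline,unfoldedBaseline numeric(2): intercept (signal at
#'   0 deg C) and slope per deg C.
#' @param temps temperature grid (deg C).
#' @param noiseSd additive Gaussian noise standard deviation (signal units).
#' @param seed integer RNG seed (only used when `noiseSd > 0`).
#' @return A [MeltCurve-class].
#' @examples
#' m <- simulateMelt(62, 400, c(-20, 0), c(-2, 0), temps = 10:80,
#'                   noiseSd = 0.36, seed = 4)
#' @export
simulateMelt <- function(midpoint, dH, foldedBaseline = c(1, 0),
                         unfoldedBaseline = c(0, 0), temps,
                         noiseSd = 0, seed = 1) {
  if (dH <= 0) stop("dH must be positive")
  if (midpoint < min(temps) || midpoint > max(temps))
    stop("midpoint must lie inside the temperature range")
  fu <- fractionUnfolded(temps, midpoint, dH)
  signal <- (1 - fu) * (foldedBaseline[1] + foldedBaseline[2] * temps) +
    fu * (unfoldedBaseline[1] + unfoldedBaseline[2] * temps)
  if (noiseSd > 0) {
    set.seed(.checkSeed(seed))
    signal <- signal + stats::rnorm(length(signal), sd = noiseSd)
  }
  MeltCurve(temps, signal)
}
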