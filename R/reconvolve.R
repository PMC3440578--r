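## Reconvolution forward model shared by the generators and the fitters.
## Generator-fitter consistency relies on both sides going through
## .convolveIRF() on the same channel-midpoint sampling.

# Linear (zero-padded FFT) convolution of a normalized IRF with one or more
# decay curves sampled at channel midpoints.  `decays` is a vector or an
# n x k matrix; returns the same shape, truncated to the first n channels.
.convolveIRF <- function(irfNorm, decays) {
  n <- length(irfNorm)
  d <- as.matrix(decays)
  stopifnot(nrow(d) == n)
  P <- stats::fft(c(irfNorm, rep(0, n)))
  out <- matrix(0, n, ncol(d))
  for (i in seq_len(ncol(d))) {
    Y <- stats::fft(c(d[, i], rep(0, n)))
    out[, i] <- pmax(Re(stats::fft(P * Y, inverse = TRUE)) / (2 * n), 0)[1:n]
  }
  if (is.matrix(decays)) out else out[, 1]
}

# Normalized IRF with optional sub-channel shift by linear interpolation.
.irfProfile <- function(irf, shift = 0) {
  if (sum(irf) <= 0) stop("IRF is all zero")
  p <- irf / sum(irf)
  if (shift != 0) {
    k <- seq_along(p)
    p <- stats::approx(k, p, xout = k - shift, yleft = 0, yright = 0)$y
    s <- sum(p)
    if (s <= 0) stop("IRF shift moved all mass outside the window")
    p <- p / s
  }
  p
}

# Multi-exponential decay sampled at channel midpoints; returns n x k matrix
# of exp(-t/tau) columns (unit amplitude).
.expBasis <- function(taus, nChannels, channelWidth) {
  t <- (seq_len(nChannels) - 0.5) * channelWidth
  vapply(taus, function(tau) exp(-t / tau), numeric(nChannels))
}

#' Reconvolve a discrete decay model with a measured IRF
#'
#' Forward model of iterative-reconvolution lifetime fitting: the normalized
#' IRF (optionally shifted by a sub-channel amount via linear interpolation)
#' is convolved with the multi-exponential decay sampled at channel midpoints,
#' scaled, and the expected flat background of `hist` is added.
#'
#' @param components a [DecayComponents-class] model.
#' @param hist a [TCSPCHistogram-class] supplying the IRF, grid and
#'   background.
#' @param shift sub-channel IRF shift in channels (default 0).
#' @param scale total model amplitude in counts (default 1).
#' @return Numeric vector of expected counts per channel.
#' @examples
#' irf <- makeIRF(peakTime = 1, fwhm = 0.1, nChannels = 256,
#'                channelWidth = 0.05)
#' cmp <- DecayComponents(1, 2)
#' m <- reconvolve(cmp, irf, scale = 1e5)
#' @export
reconvolve <- function(components, hist, shift = 0, scale = 1) {
  stopifnot(is(components, "DecayComponents"), is(hist, "TCSPCHistogram"))
  validObject(components)
  p <- .irfProfile(hist@irf, shift)
  B <- .expBasis(components@lifetimes, length(p), hist@channelWidth)
  d <- as.vector(B %*% components@amplitudes)
  scale * .convolveIRF(p, d) + hist@background
}
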