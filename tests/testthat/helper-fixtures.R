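# Shared fixtures, built in code at test time.

# Gaussian IRF on a small grid (1024 x 0.02 ns by default).
smallIRF <- function(nChannels = 1024, channelWidth = 0.02, peak = 1,
                     fwhm = 0.2) {
  makeIRF(peak, fwhm, nChannels, channelWidth)
}

# Delta IRF with all mass in one channel (channel 1 by default), so
# convolution is the identity (up to a shift).
deltaIRF <- function(nChannels = 1024, channelWidth = 0.02, atChannel = 1L,
                     total = 1e6) {
  irf <- numeric(nChannels)
  irf[atChannel] <- total
  TCSPCHistogram(irf = irf, channelWidth = channelWidth)
}

# Noise-free "measured" histogram: the reconvolved expectation rounded to
# integer counts at a scale large enough that rounding is negligible.
noiselessDecay <- function(components, irf, scale = 1e7) {
  m <- reconvolve(components, irf, scale = scale)
  TCSPCHistogram(counts = round(m), irf = irfCounts(irf),
                 channelWidth = channelWidth(irf),
                 background = background(irf))
}

# Noise-free polarized pair built through the same forward model the
# generator uses (zero-padded FFT convolution at channel midpoints).
noiselessPolarized <- function(components, aniso, irf, gFactor = 1,
                               scale = 1e7) {
  n <- length(irfCounts(irf))
  dt <- channelWidth(irf)
  t <- (seq_len(n) - 0.5) * dt
  p <- irfCounts(irf) / sum(irfCounts(irf))
  I <- colSums(amplitudes(components) *
                 t(outer(t, lifetimes(components), function(t, tau)
                   exp(-t / tau))))
  r <- colSums(betas(aniso) *
                 t(outer(t, thetas(aniso), function(t, th) exp(-t / th))))
  P <- stats::fft(c(p, rep(0, n)))
  cv <- function(d)
    pmax(Re(stats::fft(P * stats::fft(c(d, rep(0, n))), inverse = TRUE)) /
           (2 * n), 0)[1:n]
  PolarizedDecays(
    ivv = TCSPCHistogram(round(scale * cv(I * (1 + 2 * r) / 3)),
                         irfCounts(irf), dt),
    ivh = TCSPCHistogram(round(scale * cv(I * (1 - r) / (3 * gFactor))),
                         irfCounts(irf), dt),
    gFactor = gFactor)
}

ntdRef <- function() dre2Reference("ntd")
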