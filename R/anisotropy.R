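## Anisotropy decay construction, associative-model fitting, and the
## wobbling-in-cone angle.

#' Construct the anisotropy decay from polarized components
#'
#' Computes `r(t) = (Ivv - G Ivh) / (Ivv + 2 G Ivh)` and the total intensity
#' `Ivv + 2 G Ivh` per channel.  Channels whose total is below `minTotal`
#' counts are masked (`r = NA`) because the ratio is statistically
#' meaningless there.
#'
#' @param pol a [PolarizedDecays-class].
#' @param minTotal minimum total counts per channel (default 10).
#' @return A `data.frame` with columns `time` (ns), `total`, and `r`.
#' @export
anisotropyCurve <- function(pol, minTotal = 10) {
  stopifnot(is(pol, "PolarizedDecays"))
  G <- pol@gFactor
  if (G <= 0) stop("gFactor must be positive")
  vv <- pol@ivv@counts
  vh <- pol@ivh@counts
  total <- vv + 2 * G * vh
  r <- (vv - G * vh) / total
  r[total < minTotal] <- NA_real_
  data.frame(time = timeAxis(pol), total = total, r = r)
}

#' Total time-zero anisotropy
#'
#' The time-zero anisotropy `r(t=0) = sum(beta_i)` of a rotational model.
#'
#' @param aniso an [AnisotropyComponents-class] (or [AnisotropyFit-class]).
#' @return Dimensionless total anisotropy; 0 for an empty model.
#' @examples
#' totalAnisotropy(AnisotropyComponents(c(0.041, 0.010, 0.156),
#'                                      c(0.17, 0.9, 8.6)))
#' @export
totalAnisotropy <- function(aniso) {
  if (is(aniso, "AnisotropyFit")) aniso <- aniso@components
  stopifnot(is(aniso, "AnisotropyComponents"))
  sum(aniso@betas)
}

#' Fit rotational correlation times under the associative model
#'
#' Simultaneously fits the reconvolved forward models of both polarized
#' components, `Ivv = S (*) [I(t)(1 + 2 r(t))/3]` and
#' `Ivh = S (*) [I(t)(1 - r(t))/(3G)]`, sharing the intensity decay `I(t)`
#' (the previously fitted lifetimes, held fixed) and
#' `r(t) = sum(beta_i exp(-t/theta_i))` — the associative assumption that
#' every lifetime carries all rotational correlation times.  Fitting is done
#' on the polarized counts (not on the ratio r(t)) so Poisson weighting
#' remains valid.  The correlation times are optimized by
#' Levenberg-Marquardt on log(theta) with the scale and the beta amplitudes
#' profiled out linearly; near-degenerate or zero-amplitude rotors flag the
#' fit.
#'
#' @param pol a [PolarizedDecays-class].
#' @param lifetimes a [DecayComponents-class] fitted from the total
#'   intensity decay.
#' @param nRot number of rotational components (1 to 3).
#' @param r0 fundamental anisotropy carried into the result (default 0.185).
#' @param init optional numeric vector of starting correlation times (ns).
#' @param fitStart first fitted channel (default: IRF peak channel).
#' @param maxIterations Levenberg-Marquardt iteration cap.
#' @return An [AnisotropyFit-class].
#' @export
fitAnisotropy <- function(pol, lifetimes, nRot, r0 = 0.185, init = NULL,
                          fitStart = NULL, maxIterations = 200) {
  stopifnot(is(pol, "PolarizedDecays"), is(lifetimes, "DecayComponents"))
  if (nRot < 1 || nRot > 3) stop("nRot must be between 1 and 3")
  G <- pol@gFactor
  n <- length(pol@ivv@irf)
  dt <- pol@ivv@channelWidth
  p <- .irfProfile(pol@ivv@irf)
  if (is.null(fitStart)) fitStart <- which.max(pol@ivv@irf)
  idx <- fitStart:n
  I <- as.vector(.expBasis(lifetimes@lifetimes, n, dt) %*%
                   lifetimes@amplitudes)
  yvv <- pol@ivv@counts[idx] - pol@ivv@background
  yvh <- pol@ivh@counts[idx] - pol@ivh@background
  y <- c(yvv, yvh)
  w <- 1 / pmax(c(pol@ivv@counts[idx], pol@ivh@counts[idx]), 1)

  # Bounded parameterization: (log theta_i, beta_i) with beta in [0, 0.4],
  # the single overall scale profiled analytically.  A free linear solve of
  # the beta amplitudes is weakly identified at low counts (a slow rotor
  # trades off against the scale), so the physical box on beta is part of
  # the optimization, not a post-hoc clip.
  modelFor <- function(thetas, bet) {
    r <- as.vector(.expBasis(thetas, n, dt) %*% bet)
    mvv <- .convolveIRF(p, I * (1 + 2 * r) / 3)
    mvh <- .convolveIRF(p, I * (1 - r) / (3 * G))
    c(mvv[idx], mvh[idx])
  }
  residFor <- function(par) {
    k <- nRot
    mhat <- modelFor(exp(par[1:k]), par[(k + 1):(2 * k)])
    c0 <- sum(w * y * mhat) / sum(w * mhat * mhat)
    sqrt(w) * (y - c0 * mhat)
  }

  # crude r(0) estimate from the early-time ratio seeds the beta starts
  early <- seq_len(min(50L, length(idx)))
  r0est <- sum(yvv[early] - G * yvh[early]) /
    max(sum(yvv[early] + 2 * G * yvh[early]), 1)
  r0est <- min(max(r0est, 0.02), 0.35)
  thetaStarts <- list(exp(seq(log(5 * dt), log(0.5 * n * dt),
                              length.out = nRot + 2))[seq_len(nRot) + 1])
  if (!is.null(init)) thetaStarts <- c(list(as.numeric(init)), thetaStarts)
  lower <- c(rep(log(dt / 2), nRot), rep(0, nRot))
  upper <- c(rep(log(20 * n * dt), nRot), rep(0.4, nRot))
  best <- NULL
  for (s in thetaStarts) {
    fit <- minpack.lm::nls.lm(
      par = c(log(s), rep(r0est / nRot, nRot)),
      fn = residFor, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = maxIterations, ftol = 1e-14, ptol = 1e-14, gtol = 0))
    if (is.null(best) || fit$deviance < best$deviance - 1e-12) best <- fit
  }

  thetas <- exp(best$par[1:nRot])
  bet <- best$par[(nRot + 1):(2 * nRot)]
  mhat <- modelFor(thetas, bet)
  scale <- sum(w * y * mhat) / sum(w * mhat * mhat)
  if (scale <= 0) stop("anisotropy fit collapsed: non-positive intensity scale")
  ssr <- sum(w * (y - scale * mhat)^2)
  dof <- max(length(y) - (2 * nRot + 1), 1)
  flagged <- FALSE
  bet <- pmax(bet, 0)
  o <- order(thetas)
  thetas <- thetas[o]; bet <- bet[o]
  i <- 1L
  while (i < length(thetas)) {
    if (abs(thetas[i + 1] - thetas[i]) / thetas[i + 1] < 0.05) {
      bsum <- bet[i] + bet[i + 1]
      thetas[i] <- if (bsum > 0)
        (bet[i] * thetas[i] + bet[i + 1] * thetas[i + 1]) / bsum
      else sqrt(thetas[i] * thetas[i + 1])
      bet[i] <- bsum
      thetas <- thetas[-(i + 1)]; bet <- bet[-(i + 1)]
      flagged <- TRUE
    } else i <- i + 1L
  }
  if (any(bet < 1e-4 * max(bet))) flagged <- TRUE
  if (sum(bet) > 0.4) {  # unphysical total anisotropy: cap and flag
    bet <- bet * 0.4 / sum(bet)
    flagged <- TRUE
  }
  converged <- best$info %in% 1:3 && best$niter < maxIterations
  new("AnisotropyFit",
      components = AnisotropyComponents(bet, thetas, r0 = r0),
      chi2Reduced = ssr / dof, scale = scale,
      converged = converged && !flagged)
}

#' Wobbling-in-cone semi-angle from the slow anisotropy amplitude
#'
#' Solves the cone model relation
#' `beta_slow / r0 = [1/2 cos(w) (1 + cos(w))]^2` for the cone semi-angle
#' `w` in `[0, 90]` degrees.  With `q = sqrt(beta_slow / r0)` the relation is
#' the quadratic `c^2 + c - 2q = 0` in `c = cos(w)`, whose admissible root is
#' `c = (-1 + sqrt(1 + 8q)) / 2`.
#'
#' @param betaSlow slow-component anisotropy amplitude (0 <= betaSlow <= r0).
#' @param r0 fundamental anisotropy (default 0.185).
#' @return Cone semi-angle in degrees: 0 when `betaSlow == r0` (no wobble),
#'   90 when `betaSlow == 0` (unrestricted).
#' @examples
#' coneAngle(0.156)          # ~19 degrees
#' coneAngle(0.091, 0.185)   # ~38 degrees
#' @export
coneAngle <- function(betaSlow, r0 = 0.185) {
  if (any(r0 <= 0)) stop("r0 must be positive")
  if (any(betaSlow < 0)) stop("betaSlow must be non-negative")
  if (any(betaSlow > r0 + 1e-12))
    stop("betaSlow exceeds r0: cone angle undefined")
  q <- sqrt(pmin(betaSlow / r0, 1))
  cw <- (-1 + sqrt(1 + 8 * q)) / 2
  acos(pmin(pmax(cw, -1), 1)) * 180 / pi
}
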