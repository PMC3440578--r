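## Maximum-entropy inversion of decay histograms: maximize the
## Skilling-Jaynes entropy S = sum(a - m - a log(a/m)) subject to a
## chi-squared constraint on the reconvolved mixture over a logarithmic
## lifetime grid.  Solved as a sequence of unconstrained problems
## min 0.5 chi^2 - mu S on log-amplitudes (L-BFGS-B with analytic gradient),
## with an outer bisection on the Lagrange multiplier mu so that
## chi^2 hits the target; chi^2(mu) is monotone increasing in mu.

#' Maximum-entropy lifetime distribution of a TCSPC decay
#'
#' Recovers a non-negative amplitude density over a logarithmic lifetime grid
#' whose reconvolved mixture matches the decay histogram at the target
#' chi-squared.  Among all feasible densities the solver returns the one of
#' maximum Skilling-Jaynes entropy relative to the prior, i.e. the least
#' committal distribution consistent with the data.  If the prior itself
#' already satisfies the constraint the prior is returned (status
#' `"prior"`); if the constraint cannot be reached the best-chi2 solution is
#' returned flagged `"infeasible"`.
#'
#' @param hist a [TCSPCHistogram-class] with counts and IRF.
#' @param settings an [MEMSettings-class]; the default uses a flat prior
#'   scaled to the observed counts and a chi-squared target equal to the
#'   number of fitted channels (reduced chi-squared 1).
#' @param tauBounds lifetime grid bounds in ns (default `c(0.01, 30)`,
#'   bracketing tryptophan lifetimes with margin).
#' @param nNodes number of grid nodes (default 150).
#' @param fitStart first fitted channel (default: IRF peak channel).
#' @return A [LifetimeDistribution-class].
#' @examples
#' irf <- makeIRF(1, 0.2, nChannels = 1024, channelWidth = 0.02)
#' hist <- simulateDecay(DecayComponents(1, 2), irf, 1e5, seed = 1)
#' dist <- fitMEM(hist, nNodes = 60)
#' chi2Reduced(dist)
#' @export
fitMEM <- function(hist, settings = MEMSettings(), tauBounds = c(0.01, 30),
                   nNodes = 150, fitStart = NULL) {
  stopifnot(is(hist, "TCSPCHistogram"), is(settings, "MEMSettings"))
  if (!length(hist@counts)) stop("histogram has no counts to fit")
  if (tauBounds[1] <= 0 || tauBounds[2] <= tauBounds[1])
    stop("tauBounds must be an increasing positive pair")
  y <- hist@counts
  n <- length(y)
  p <- .irfProfile(hist@irf)
  if (is.null(fitStart)) fitStart <- which.max(hist@irf)
  idx <- fitStart:n
  grid <- exp(seq(log(tauBounds[1]), log(tauBounds[2]), length.out = nNodes))
  C <- .convolveIRF(p, .expBasis(grid, n, hist@channelWidth))[idx, ,
                                                              drop = FALSE]
  w <- 1 / pmax(y[idx], 1)
  yfit <- y[idx] - hist@background
  target <- if (is.na(settings@chi2Target)) length(idx)
            else settings@chi2Target

  m <- settings@prior
  if (!length(m)) {
    # Flat uninformative prior two orders of magnitude below the data scale:
    # nodes the data do not constrain relax to the prior level, so its total
    # must be small against the signal or it contaminates the recovered
    # amplitude distribution, yet large enough to keep the inner solver
    # well-conditioned.
    total <- max(sum(yfit), 1)
    m <- rep(0.01 * total / sum(colSums(C)), nNodes)
  } else if (length(m) != nNodes)
    stop("prior length must match the number of grid nodes")
  m <- pmax(m, 1e-300)

  Cw <- C * w   # rows pre-scaled for the gradient
  chi2Of <- function(a) {
    r <- as.vector(C %*% a) - yfit
    sum(w * r * r)
  }
  solveMu <- function(mu, u0) {
    obj <- function(u) {
      a <- exp(u)
      r <- as.vector(C %*% a) - yfit
      0.5 * sum(w * r * r) - mu * sum(a - m - a * log(a / m))
    }
    grad <- function(u) {
      a <- exp(u)
      r <- as.vector(C %*% a) - yfit
      a * (as.vector(crossprod(Cw, r)) + mu * log(a / m))
    }
    stats::optim(u0, obj, grad, method = "L-BFGS-B",
                 lower = -700, upper = log(2 * sum(abs(yfit)) + 10),
                 control = list(maxit = settings@maxIterations,
                                factr = 10,
                                pgtol = settings@gradTol))$par
  }

  chi2Prior <- chi2Of(m)
  if (chi2Prior <= target)
    return(new("LifetimeDistribution", tauGrid = grid, density = m,
               chi2Reduced = chi2Prior / length(idx), status = "prior"))

  # Bracket mu: chi2 increases with mu (more entropy weight pulls the
  # solution toward the prior, away from the data).
  # chi2(mu) is monotone increasing in mu.  Walk mu down from the prior
  # side with warm starts, stopping as soon as the constraint is met, then
  # bisect in log(mu); the ill-conditioned mu -> 0 problem is only solved
  # when the data truly cannot reach the target (infeasible case).
  mu <- 1
  u <- solveMu(mu, log(m))
  chi2 <- chi2Of(exp(u))
  if (chi2 > target) {
    repeat {
      muNext <- mu / 10
      uNext <- solveMu(muNext, u)
      chi2Next <- chi2Of(exp(uNext))
      if (chi2Next <= target) { loMu <- muNext; hiMu <- mu; u <- uNext; break }
      mu <- muNext; u <- uNext; chi2 <- chi2Next
      if (mu < 1e-9)
        return(new("LifetimeDistribution", tauGrid = grid, density = exp(u),
                   chi2Reduced = chi2 / length(idx), status = "infeasible"))
    }
  } else {
    repeat {
      muNext <- mu * 10
      uNext <- solveMu(muNext, u)
      chi2Next <- chi2Of(exp(uNext))
      if (chi2Next > target) { loMu <- mu; hiMu <- muNext; break }
      mu <- muNext; u <- uNext
      if (mu > 1e12) { loMu <- mu; hiMu <- mu; break }
    }
  }
  lo <- log(loMu); hi <- log(hiMu)
  for (it in seq_len(40)) {
    if (hi - lo < 1e-12) break
    mid <- (lo + hi) / 2
    u <- solveMu(exp(mid), u)
    chi2 <- chi2Of(exp(u))
    if (abs(chi2 - target) / target < settings@tol) break
    if (chi2 > target) hi <- mid else lo <- mid
  }
  a <- exp(u)
  new("LifetimeDistribution", tauGrid = grid, density = a,
      chi2Reduced = chi2Of(a) / length(idx), status = "converged")
}

#' Reduce a lifetime distribution to discrete components
#'
#' Segments the grid into contiguous regions separated by zero-density
#' valleys (density below `threshold` times the maximum); each region
#' contributes one component whose amplitude is the renormalized summed
#' weight and whose lifetime is the weight-weighted geometric mean, matching
#' how discrete values are conventionally read off MEM distributions.
#'
#' @param dist a [LifetimeDistribution-class].
#' @param threshold valley threshold relative to the density maximum
#'   (default 1e-3).
#' @return A [DecayComponents-class].
#' @export
extractComponents <- function(dist, threshold = 1e-3) {
  stopifnot(is(dist, "LifetimeDistribution"))
  a <- dist@density
  if (!any(a > 0)) stop("empty distribution: no positive density")
  live <- a >= threshold * max(a)
  runs <- rle(live)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  amps <- numeric(0); taus <- numeric(0)
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    seg <- starts[k]:ends[k]
    wseg <- a[seg]
    amps <- c(amps, sum(wseg))
    taus <- c(taus, exp(sum(wseg * log(dist@tauGrid[seg])) / sum(wseg)))
  }
  DecayComponents(amps, taus, normalize = TRUE)
}
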