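## Two-state van't Hoff analysis of thermal denaturation traces.

#' Fraction unfolded in the two-state van't Hoff model
#'
#' `K = exp(-dH/R (1/T - 1/Tm))` with temperatures in kelvin and
#' `fu = K / (1 + K)`; at the midpoint `fu = 0.5` exactly.
#'
#' @param temperature temperature(s) in deg C.
#' @param midpoint melting midpoint Tm (deg C).
#' @param dH van't Hoff enthalpy (kJ/mol, > 0).
#' @return Unfolded fraction(s) in (0, 1).
#' @examples
#' fractionUnfolded(62, 62, 400)  # 0.5
#' @export
fractionUnfolded <- function(temperature, midpoint, dH) {
  if (any(dH <= 0)) stop("dH must be positive")
  TK <- temperature + 273.15
  TmK <- midpoint + 273.15
  K <- exp(-(dH * 1000 / .const$R_gas) * (1 / TK - 1 / TmK))
  K / (1 + K)
}

#' Fit a two-state thermal denaturation curve
#'
#' Nonlinear least squares of
#' `signal(T) = (1 - fu(T)) basef(T) + fu(T) baseu(T)` with linear (or flat)
#' baselines.  The baselines are profiled out linearly for each candidate
#' (Tm, dH); the outer optimization is Levenberg-Marquardt on (Tm, log dH),
#' initialized at the temperature of the maximum smoothed |d signal / d T|.
#' Fitting runs in kelvin internally; results are reported in deg C.  The
#' recovered midpoint is an apparent Tm: partial irreversibility of a real
#' melt violates strict two-state reversibility, which this model does not
#' attempt to capture.  Featureless (baseline-dominated) data is flagged
#' non-convergent rather than raising an error.
#'
#' @param curve a [MeltCurve-class] spanning at least 20 deg C.
#' @param baselines `"flat"` (intercepts only) or `"sloped"` (intercept and
#'   slope per state).
#' @param init optional numeric(2): starting `c(midpoint, dH)`.
#' @return A [TwoStateFit-class].
#' @examples
#' m <- simulateMelt(62, 400, c(-20, 0), c(-2, 0), temps = 10:80)
#' meltingPoint(fitTwoState(m))
#' @export
fitTwoState <- function(curve, baselines = c("sloped", "flat"), init = NULL) {
  stopifnot(is(curve, "MeltCurve"))
  baselines <- match.arg(baselines)
  Tc <- curve@temperature
  y <- curve@signal
  if (diff(range(Tc)) < 20)
    stop("curve must span at least 20 deg C")

  basisFor <- function(tm, dH) {
    fu <- fractionUnfolded(Tc, tm, dH)
    if (baselines == "flat") cbind(1 - fu, fu)
    else cbind(1 - fu, (1 - fu) * Tc, fu, fu * Tc)
  }
  solveLin <- function(M) {
    cf <- qr.coef(qr(M), y)
    cf[is.na(cf)] <- 0
    cf
  }
  residFor <- function(par) {
    M <- basisFor(par[1], exp(par[2]))
    y - as.vector(M %*% solveLin(M))
  }

  if (is.null(init)) {
    # derivative-maximum initializer on a lightly smoothed trace
    k <- min(5L, length(y))
    ys <- stats::filter(y, rep(1 / k, k), sides = 2)
    ys[is.na(ys)] <- y[is.na(ys)]
    slope <- abs(diff(as.numeric(ys)) / diff(Tc))
    tm0 <- Tc[which.max(slope)]
    tm0 <- min(max(tm0, min(Tc) + 1), max(Tc) - 1)
    init <- c(tm0, 300)
  }
  fit <- minpack.lm::nls.lm(
    par = c(init[1], log(init[2])), fn = residFor,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  tm <- fit$par[1]
  dH <- exp(fit$par[2])
  M <- basisFor(tm, dH)
  cf <- solveLin(M)
  res <- y - as.vector(M %*% cf)
  if (baselines == "flat") {
    bf <- c(cf[1], 0); bu <- c(cf[2], 0)
  } else {
    bf <- cf[1:2]; bu <- cf[3:4]
  }
  rsd <- stats::sd(res)
  # transition amplitude at the midpoint vs noise: featureless data flag
  amp <- abs((bu[1] + bu[2] * tm) - (bf[1] + bf[2] * tm))
  converged <- fit$info %in% 1:3 && tm > min(Tc) && tm < max(Tc) &&
    (rsd == 0 || amp > 2 * rsd)
  new("TwoStateFit", tm = tm, dH = dH, baselineFolded = as.numeric(bf),
      baselineUnfolded = as.numeric(bu), residualSd = rsd,
      converged = isTRUE(converged))
}
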