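## Closed-form hydrodynamic predictions (CGS internally; CODATA 2018
## constants; standard conditions are water at 20 C, the sednterp
## convention: eta = 0.01002 P, rho = 0.99823 g/mL).

#' Anhydrous sphere radius of a protein
#'
#' Radius of the minimal (anhydrous) sphere of molar mass `mass` and partial
#' specific volume `vbar`: `R0 = (3 M vbar / (4 pi N_A))^(1/3)`.
#'
#' @param mass molar mass (Da).
#' @param vbar partial specific volume (mL/g).
#' @return Radius in nm.
#' @examples
#' anhydrousRadius(15000, 0.753)  # ~1.65 nm
#' @export
anhydrousRadius <- function(mass, vbar) {
  if (any(mass <= 0) || any(vbar <= 0)) stop("mass and vbar must be positive")
  (3 * mass * vbar / (4 * pi * .const$N_A))^(1 / 3) * 1e7  # cm -> nm
}

#' Sedimentation coefficient from the Svedberg relation
#'
#' `s = M (1 - vbar rho) / (N_A (f/f0) 6 pi eta R0)` with `R0` the anhydrous
#' sphere radius, reported in svedberg (1e-13 s).
#'
#' @param spec a [HydroSpec-class].
#' @return Sedimentation coefficient in S.  Neutral buoyancy
#'   (`vbar * rho == 1`) returns 0 with a warning.
#' @examples
#' sedimentationCoefficient(HydroSpec(15000, frictionalRatio = 1.1))  # ~1.8 S
#' @export
sedimentationCoefficient <- function(spec) {
  stopifnot(is(spec, "HydroSpec"))
  buoy <- 1 - spec@vbar * spec@density
  if (abs(buoy) < 1e-12) {
    warning("neutral buoyancy: sedimentation coefficient is zero")
    return(0)
  }
  r0cm <- anhydrousRadius(spec@mass, spec@vbar) * 1e-7
  s <- spec@mass * buoy /
    (.const$N_A * spec@frictionalRatio * 6 * pi * spec@viscosity * r0cm)
  s / 1e-13
}

#' Standardize an observed sedimentation coefficient to water at 20 C
#'
#' `s20w = s_obs (eta_buffer / eta_20w) (1 - vbar rho)_20w /
#' (1 - vbar rho)_buffer`.
#'
#' @param sObs observed sedimentation coefficient (S).
#' @param buffer a [HydroSpec-class] carrying the buffer viscosity and
#'   density.
#' @param vbar partial specific volume (mL/g); defaults to the value in
#'   `buffer`.
#' @return Standardized s20,w in S.
#' @export
s20wCorrection <- function(sObs, buffer, vbar = buffer@vbar) {
  stopifnot(is(buffer, "HydroSpec"))
  bStd <- 1 - vbar * .const$rho_20w
  bBuf <- 1 - vbar * buffer@density
  if (abs(bStd) < 1e-12 || abs(bBuf) < 1e-12)
    stop("neutral buoyancy in buffer or standard conditions")
  sObs * (buffer@viscosity / .const$eta_20w) * (bStd / bBuf)
}

#' Rotational correlation time of a hydrated sphere
#'
#' Stokes-Einstein-Debye: `theta = eta V_h / (k_B T)` with the hydrated
#' volume `V_h` per molecule determined by an explicit hydration convention
#' applied to the `hydration` slot of `spec`:
#' \describe{
#'   \item{`"volume-fraction"`}{`V_h = (M / N_A) vbar (1 + phi)` — hydration
#'     as a fractional volume increment.}
#'   \item{`"mass-hydration"`}{`V_h = (M / N_A) (vbar + delta)` — hydration
#'     as grams of water (specific volume 1.0 mL/g) per gram of protein.}
#'   \item{`"radius-scale"`}{`V_h = (M / N_A) vbar (1 + eps)^3` — hydration
#'     as a fractional increase of the anhydrous radius.}
#' }
#' A loosely stated "hydration radius of 40%" maps to materially different
#' volumes under these readings (the three differ by up to a factor of two),
#' so the convention must be chosen explicitly; it is recorded in the
#' `"convention"` attribute of the result.
#'
#' @param spec a [HydroSpec-class] (the `hydration` slot supplies phi,
#'   delta or eps).
#' @param convention one of `"volume-fraction"`, `"mass-hydration"`,
#'   `"radius-scale"`.
#' @return Rotational correlation time in ns, with attribute `"convention"`.
#' @examples
#' rotationalCorrelation(HydroSpec(15000), "volume-fraction")  # anhydrous ~4.6
#' @export
rotationalCorrelation <- function(spec,
                                  convention = c("volume-fraction",
                                                 "mass-hydration",
                                                 "radius-scale")) {
  stopifnot(is(spec, "HydroSpec"))
  convention <- match.arg(convention)
  h <- spec@hydration
  vml <- spec@mass / .const$N_A *   # mL per molecule
    switch(convention,
           "volume-fraction" = spec@vbar * (1 + h),
           "mass-hydration"  = spec@vbar + h,
           "radius-scale"    = spec@vbar * (1 + h)^3)
  etaSI <- spec@viscosity * 0.1     # poise -> Pa s
  theta <- etaSI * (vml * 1e-6) / (.const$k_B * spec@temperature) * 1e9
  structure(theta, convention = convention)
}
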