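# Independent scripted evaluations of each formula (written out inline with
# their own constants) serve as the oracle for the closed-form operations.

test_that("anhydrousRadius evaluates the minimal-sphere formula", {
  NAv <- 6.02214076e23
  r <- (3 * 15000 * 0.753 / (4 * pi * NAv))^(1 / 3) * 1e7
  expect_equal(anhydrousRadius(15000, 0.753), r, tolerance = 1e-9)
  expect_equal(anhydrousRadius(15000, 0.753), 1.648, tolerance = 1e-3)
  expect_equal(anhydrousRadius(8 * 15000, 0.753),
               2 * anhydrousRadius(15000, 0.753), tolerance = 1e-12)
  expect_lt(anhydrousRadius(1e-6, 0.753), 0.001)
})

test_that("sedimentationCoefficient reproduces the Svedberg prediction", {
  spec <- HydroSpec(15000, vbar = 0.753, viscosity = 0.01002,
                    density = 0.99823, frictionalRatio = 1.1)
  s <- sedimentationCoefficient(spec)
  # independent evaluation
  NAv <- 6.02214076e23
  r0 <- (3 * 15000 * 0.753 / (4 * pi * NAv))^(1 / 3)
  sref <- 15000 * (1 - 0.753 * 0.99823) /
    (NAv * 1.1 * 6 * pi * 0.01002 * r0) / 1e-13
  expect_equal(s, sref, tolerance = 1e-9)
  expect_lt(abs(s - 1.8), 0.1)

  # f/f0 enters as an exact inverse factor
  s1 <- sedimentationCoefficient(HydroSpec(15000, frictionalRatio = 1))
  expect_equal(s1 / s, 1.1, tolerance = 1e-12)

  # s scales as M^(2/3) at fixed vbar and f/f0
  masses <- 15000 * c(1, 2, 5, 10)
  svals <- vapply(masses, function(m)
    sedimentationCoefficient(HydroSpec(m, frictionalRatio = 1.1)),
    numeric(1))
  expect_equal(svals / svals[1], (masses / masses[1])^(2 / 3),
               tolerance = 1e-9)

  expect_warning(
    s0 <- sedimentationCoefficient(HydroSpec(15000, vbar = 1 / 0.99823)),
    "neutral buoyancy")
  expect_equal(s0, 0)
})

test_that("s20wCorrection applies the viscosity and buoyancy ratios", {
  water <- HydroSpec(15000, viscosity = 0.01002, density = 0.99823)
  expect_equal(s20wCorrection(1.7, water), 1.7, tolerance = 1e-12)

  buffer <- HydroSpec(15000, viscosity = 0.009162, density = 1.00568)
  fac <- s20wCorrection(1, buffer, vbar = 0.753)
  # independent evaluation of the two ratios
  fref <- (0.009162 / 0.01002) *
    (1 - 0.753 * 0.99823) / (1 - 0.753 * 1.00568)
  expect_equal(fac, fref, tolerance = 1e-12)
  expect_equal(fac, 0.9355, tolerance = 1e-4)
  expect_equal(s20wCorrection(3.4, buffer), 3.4 * fac, tolerance = 1e-12)
  expect_error(s20wCorrection(1, buffer, vbar = 1 / 1.00568), "neutral")
})

test_that("rotationalCorrelation follows Stokes-Einstein-Debye", {
  kB <- 1.380649e-23; NAv <- 6.02214076e23
  anh <- rotationalCorrelation(HydroSpec(15000), "volume-fraction")
  ref <- (0.01002 * 0.1) * (15000 / NAv * 0.753 * 1e-6) / (kB * 293.15) * 1e9
  expect_equal(as.numeric(anh), ref, tolerance = 1e-9)
  expect_equal(as.numeric(anh), 4.64, tolerance = 1e-2)
  expect_equal(attr(anh, "convention"), "volume-fraction")

  # hydration conventions scale the anhydrous value exactly as documented
  rs <- rotationalCorrelation(HydroSpec(15000, hydration = 0.4),
                              "radius-scale")
  expect_equal(as.numeric(rs) / as.numeric(anh), 1.4^3, tolerance = 1e-12)
  mh <- rotationalCorrelation(HydroSpec(15000, hydration = 0.4),
                              "mass-hydration")
  expect_equal(as.numeric(mh) / as.numeric(anh), (0.753 + 0.4) / 0.753,
               tolerance = 1e-12)
  vf <- rotationalCorrelation(HydroSpec(15000, hydration = 0.4),
                              "volume-fraction")
  expect_equal(as.numeric(vf) / as.numeric(anh), 1.4, tolerance = 1e-12)

  # theta proportional to eta / T; mass ratio 38/15 at matched conventions
  hot <- rotationalCorrelation(HydroSpec(15000, viscosity = 0.02,
                                         temperature = 310), "volume-fraction")
  expect_equal(as.numeric(hot) / as.numeric(anh),
               (0.02 / 0.01002) * (293.15 / 310), tolerance = 1e-12)
  big <- rotationalCorrelation(HydroSpec(38000), "volume-fraction")
  expect_equal(as.numeric(big) / as.numeric(anh), 38 / 15,
               tolerance = 1e-12)

  expect_error(rotationalCorrelation(HydroSpec(15000), "bogus"))
})
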