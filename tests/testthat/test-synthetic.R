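test_that("makeIRF produces a truncated Gaussian with the requested moments", {
  # delta limit: vanishing width concentrates all mass in one channel
  irf0 <- makeIRF(1, 1e-9, 256, 0.05)
  expect_equal(sum(irfCounts(irf0) > 0), 1L)
  expect_equal(which.max(irfCounts(irf0)), 20L)  # 1 ns / 0.05 = channel 20

  irf <- makeIRF(2, 0.5, 1024, 0.02)
  expect_equal(which.max(irfCounts(irf)), 100L)
  half <- irfCounts(irf) >= max(irfCounts(irf)) / 2
  expect_equal(sum(half), 25L, tolerance = 0.1)  # fwhm 0.5 ns = 25 channels
  expect_equal(sum(irfCounts(irf)), 1e6, tolerance = 1e-3)
  expect_length(decayCounts(irf), 0)

  # first moment equals the peak time within half a channel
  for (pk in c(1.5, 2, 3.07)) {
    g <- makeIRF(pk, 0.4, 1024, 0.02)
    mom <- sum(timeAxis(g) * irfCounts(g)) / sum(irfCounts(g))
    expect_lt(abs(mom - pk), 0.01)
  }

  expect_error(makeIRF(2, -1, 256, 0.05), "positive")
  expect_error(makeIRF(100, 0.5, 256, 0.05), "window")
})

test_that("simulateDecay matches its forward model and is seed-deterministic", {
  irf <- deltaIRF(2048, 0.01)
  cmp <- DecayComponents(1, 2)
  h1 <- simulateDecay(cmp, irf, 1e5, seed = 7)
  h2 <- simulateDecay(cmp, irf, 1e5, seed = 7)
  expect_identical(decayCounts(h1), decayCounts(h2))
  expect_false(identical(decayCounts(h1),
                         decayCounts(simulateDecay(cmp, irf, 1e5, seed = 8))))

  # count conservation: total ~ Poisson(total_counts)
  expect_lt(abs(sum(decayCounts(h1)) - 1e5), 4 * sqrt(1e5))

  # photon arrival-time sample mean of a tau = 2 ns decay (delta IRF, no
  # background, window >> tau)
  tbar <- sum(timeAxis(h1) * decayCounts(h1)) / sum(decayCounts(h1))
  se <- 2 / sqrt(sum(decayCounts(h1)))
  expect_lt(abs(tbar - 2), 3 * se + 0.01)

  expect_error(simulateDecay(cmp, irf, 100, seed = 1), "1e4")
})

test_that("two equal lifetimes are indistinguishable from one", {
  irf <- smallIRF()
  cmp2 <- DecayComponents(c(0.5, 0.5), c(1, 1 + 1e-9))
  h <- simulateDecay(cmp2, irf, 1e6, seed = 3)
  fit1 <- fitDecay(h, 1)
  fit2 <- fitDecay(h, 2)
  # the one-component fit explains the data as well as the two-component one
  expect_lt(chi2Reduced(fit1) / chi2Reduced(fit2), 1.01)
  expect_equal(lifetimes(fit1), 1, tolerance = 0.02)
})

test_that("simulatePolarized encodes r(t) in the vv/vh balance", {
  irf <- deltaIRF(1024, 0.02)
  cmp <- DecayComponents(1, 2.5)

  # isotropic: Ivv and G*Ivh statistically identical
  iso <- AnisotropyComponents(numeric(0), numeric(0))
  pol <- simulatePolarized(cmp, iso, irf, gFactor = 1, totalCounts = 5e5,
                           seed = 1)
  d <- sum(decayCounts(pol@ivv)) - sum(decayCounts(pol@ivh))
  expect_lt(abs(d), 4 * sqrt(1e6))

  # frozen rotor: r(t) flat at 0.2
  frozen <- AnisotropyComponents(0.2, 1e6)
  polf <- simulatePolarized(cmp, frozen, irf, gFactor = 1,
                            totalCounts = 2e6, seed = 2)
  rc <- anisotropyCurve(polf)
  keep <- !is.na(rc$r) & rc$total > 1000
  expect_equal(stats::weighted.mean(rc$r[keep], rc$total[keep]), 0.2,
               tolerance = 0.01)

  # determinism and per-detector budget
  polr <- simulatePolarized(cmp, frozen, irf, gFactor = 1,
                            totalCounts = 2e6, seed = 2)
  expect_identical(decayCounts(polr@ivv), decayCounts(polf@ivv))
  tot <- sum(decayCounts(polf@ivv)) + sum(decayCounts(polf@ivh))
  expect_lt(abs(tot - 4e6), 5 * sqrt(4e6))
})

test_that("simulateSaturation follows the saturation law", {
  # unsaturated limit: intensity / sqrt(P) -> C
  s <- simulateSaturation(3, 2.5, powers = c(1e-5, 1e-4, 1e-3, 1e-2, 0.1))
  expect_equal(intensities(s)[1] / sqrt(powers(s)[1]), 3, tolerance = 1e-4)
  # b = 2 at P = P1/2: intensity = C sqrt(P1/2) / 2
  s2 <- simulateSaturation(1, 2.5, b = 2, powers = c(0.1, 1, 2.5, 10, 100))
  expect_equal(intensities(s2)[3], sqrt(2.5) / 2, tolerance = 1e-12)
  expect_error(simulateSaturation(1, 2.5, powers = numeric(0)), "non-empty")
  s3 <- simulateSaturation(1, 2.5, powers = c(1, 2), noiseFraction = 0.05,
                           seed = 9)
  expect_identical(intensities(s3),
                   intensities(simulateSaturation(1, 2.5, powers = c(1, 2),
                                                  noiseFraction = 0.05,
                                                  seed = 9)))
})

test_that("simulateEPRLine double integral equals the requested area", {
  fg <- seq(311.3, 351.3, length.out = 2001)  # +/- 10 linewidths
  gline <- simulateEPRLine(331.3, 2, area = 1, shape = "gaussian",
                           fieldGrid = fg)
  lline <- simulateEPRLine(331.3, 2, area = 1, shape = "lorentzian",
                           fieldGrid = fg)
  expect_equal(doubleIntegral(gline), 1, tolerance = 0.005)
  expect_equal(doubleIntegral(lline), 1, tolerance = 0.005)
  # lorentzian vs gaussian at the same requested area agree within 1%
  expect_equal(doubleIntegral(lline) / doubleIntegral(gline), 1,
               tolerance = 0.01)
  # linearity: doubling the amplitude doubles the double integral
  dbl <- EPRSpectrum(fg, 2 * intensities(gline), frequencyGHz(gline))
  expect_equal(doubleIntegral(dbl), 2, tolerance = 0.01)
  # narrow grid triggers a truncation warning
  expect_warning(simulateEPRLine(331.3, 2, fieldGrid =
                                   seq(325.3, 337.3, length.out = 200)),
                 "truncation")
})

test_that("simulateMelt reproduces the two-state signal", {
  # at T = midpoint with flat baselines the signal is the baseline midpoint
  m <- simulateMelt(45, 300, c(-20, 0), c(-2, 0), temps = 10:80)
  expect_equal(m@signal[m@temperature == 45], (-20 - 2) / 2,
               tolerance = 1e-9)
  # cooperative limit: enormous dH gives a step at the midpoint
  mc <- simulateMelt(45, 1e5, c(1, 0), c(0, 0), temps = 10:80)
  expect_equal(mc@signal[m@temperature == 40], 1, tolerance = 1e-6)
  expect_equal(mc@signal[m@temperature == 50], 0, tolerance = 1e-6)
  expect_error(simulateMelt(45, -5, temps = 10:80), "positive")
  expect_error(simulateMelt(100, 300, temps = 10:80), "inside")
  m1 <- simulateMelt(45, 300, c(-20, 0), c(-2, 0), temps = 10:80,
                     noiseSd = 0.3, seed = 5)
  expect_identical(m1@signal,
                   simulateMelt(45, 300, c(-20, 0), c(-2, 0),
                                temps = 10:80, noiseSd = 0.3,
                                seed = 5)@signal)
})
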