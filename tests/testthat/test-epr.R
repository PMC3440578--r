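test_that("differenceSpectrum subtracts pointwise and cancels drift", {
  fg <- seq(311.3, 351.3, length.out = 801)
  A <- simulateEPRLine(331.3, 2, area = 1, fieldGrid = fg)
  B <- simulateEPRLine(336, 1.5, area = 0.5, fieldGrid = fg)
  z <- differenceSpectrum(A, A)
  expect_true(all(intensities(z) == 0))
  AB <- EPRSpectrum(fg, intensities(A) + intensities(B), frequencyGHz(A))
  expect_equal(intensities(differenceSpectrum(AB, A)), intensities(B),
               tolerance = 1e-12)

  # shared baseline drift cancels in the difference
  drift <- 0.05 * (fg - 331.3)
  red <- EPRSpectrum(fg, intensities(A) + intensities(B) + drift,
                     frequencyGHz(A))
  ox <- EPRSpectrum(fg, intensities(A) + drift, frequencyGHz(A))
  diff <- differenceSpectrum(red, ox)
  edge <- abs(fg - 336) > 8
  expect_lt(mean(abs(intensities(diff)[edge])), 1e-9)

  other <- EPRSpectrum(fg + 1, intensities(A), frequencyGHz(A))
  expect_error(differenceSpectrum(A, other), "grids differ")
})

test_that("gValue evaluates h nu / (mu_B B)", {
  # frozen from direct evaluation with h = 6.62607015e-34 J s,
  # mu_B = 9.2740100783e-24 J/T
  expect_equal(gValue(9.44342, 331.3), 2.036556, tolerance = 1e-6)
  expect_equal(gValue(2 * 9.44342, 2 * 331.3), gValue(9.44342, 331.3))
  B <- resonanceField(9.44342, 2.0023)
  expect_equal(gValue(9.44342, B), 2.0023, tolerance = 1e-12)
  expect_error(gValue(-1, 300), "positive")
})

test_that("doubleIntegral matches analytic derivative-line areas", {
  fg <- seq(-15, 15, length.out = 1501)
  sigma <- 1.2; A <- 2.7
  # derivative of the absorption A exp(-x^2 / 2 sigma^2):
  # its double integral is the absorption area A sigma sqrt(2 pi)
  spec <- EPRSpectrum(fg + 331, -A * fg / sigma^2 * exp(-0.5 * (fg / sigma)^2),
                      9.44342)
  expect_equal(doubleIntegral(spec), A * sigma * sqrt(2 * pi),
               tolerance = 0.001)
  spec2 <- EPRSpectrum(fg + 331, 3 * intensities(spec), 9.44342)
  expect_equal(doubleIntegral(spec2), 3 * doubleIntegral(spec),
               tolerance = 1e-9)
  # linear baseline removal restores the clean area
  drifted <- EPRSpectrum(fg + 331,
                         intensities(spec) + 0.01 * fg + 0.3, 9.44342)
  expect_equal(doubleIntegral(drifted, baseline = TRUE),
               A * sigma * sqrt(2 * pi), tolerance = 0.02)
})

test_that("spinConcentration scales by the integral ratio", {
  fg <- seq(311.3, 351.3, length.out = 1001)
  std <- simulateEPRLine(331.3, 3, area = 15, fieldGrid = fg)
  same <- simulateEPRLine(331.3, 2, area = 15, fieldGrid = fg)
  expect_equal(spinConcentration(same, std, 15), 15, tolerance = 0.02)
  sample <- simulateEPRLine(331.3, 2, area = 4, fieldGrid = fg)
  expect_equal(spinConcentration(sample, std, 15), 4, tolerance = 0.02)
  halved <- EPRSpectrum(fg, intensities(sample) / 2, 9.44342)
  expect_equal(spinConcentration(halved, std, 15), 2, tolerance = 0.02)
  zero <- EPRSpectrum(fg, rep(0, length(fg)), 9.44342)
  expect_error(spinConcentration(sample, zero, 15), "zero")
})

test_that("clustersPerProtein is the concentration ratio", {
  expect_equal(clustersPerProtein(4, 10), 0.4)
  expect_equal(clustersPerProtein(7.3, 7.3), 1)
  expect_equal(clustersPerProtein(0, 10), 0)
  expect_error(clustersPerProtein(4, 0), "positive")
})

test_that("fitSaturation recovers the saturation parameters", {
  grid <- 10^seq(log10(2e-4), log10(200), by = 0.25)
  s0 <- simulateSaturation(1, 2.5, powers = grid)
  f0 <- fitSaturation(s0)
  expect_equal(pHalf(f0), 2.5, tolerance = 1e-8)
  expect_equal(f0@scaleC, 1, tolerance = 1e-8)
  expect_equal(fitStatus(f0), "ok")

  # scale equivariance: data x 7 leaves P1/2 unchanged, scales C by 7
  s7 <- SaturationSeries(grid, 7 * intensities(s0))
  f7 <- fitSaturation(s7)
  expect_equal(pHalf(f7), 2.5, tolerance = 1e-8)
  expect_equal(f7@scaleC, 7, tolerance = 1e-8)

  # free-b fit recovers a b = 2 series
  sb <- simulateSaturation(1, 2.5, b = 2, powers = grid)
  fb <- fitSaturation(sb, fixB = NA)
  expect_equal(fb@b, 2, tolerance = 1e-6)
  expect_equal(pHalf(fb), 2.5, tolerance = 1e-6)

  # 2% noise, 20 seeds: median recovery within 10%
  ph <- vapply(1:20, function(s)
    pHalf(fitSaturation(simulateSaturation(1, 2.5, powers = grid,
                                           noiseFraction = 0.02,
                                           seed = 400 + s))),
    numeric(1))
  expect_lt(abs(stats::median(ph) / 2.5 - 1), 0.1)

  # non-saturating data flags the upper bound
  low <- simulateSaturation(1, 1e5, powers = grid)
  expect_equal(fitStatus(fitSaturation(low)), "upper-bound")
})

test_that("P1/2 recovery bias is below 5% at 1% noise", {
  grid <- 10^seq(log10(2e-4), log10(200), by = 0.25)
  ph <- vapply(1:50, function(s)
    pHalf(fitSaturation(simulateSaturation(1, 2.5, powers = grid,
                                           noiseFraction = 0.01,
                                           seed = 500 + s))),
    numeric(1))
  expect_lt(abs(mean(ph) / 2.5 - 1), 0.05)
})

test_that("classifyNuclearity separates the exemplar ranges", {
  expect_equal(classifyNuclearity(2.5), "[2Fe-2S]-like")
  expect_equal(classifyNuclearity(10.5), "[2Fe-2S]-like")
  expect_equal(classifyNuclearity(330), "[4Fe-4S]-like")
  expect_equal(classifyNuclearity(95), "[4Fe-4S]-like")
  expect_equal(classifyNuclearity(45), "indeterminate")
  expect_error(classifyNuclearity(0), "positive")
})
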