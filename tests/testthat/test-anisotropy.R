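test_that("anisotropyCurve computes r(t) from polarized counts", {
  irf <- deltaIRF(1024, 0.02)
  cmp <- DecayComponents(1, 2.5)

  iso <- AnisotropyComponents(numeric(0), numeric(0))
  pol <- simulatePolarized(cmp, iso, irf, gFactor = 1, totalCounts = 1e6,
                           seed = 1)
  rc <- anisotropyCurve(pol)
  keep <- !is.na(rc$r)
  rbar <- stats::weighted.mean(rc$r[keep], rc$total[keep])
  se <- 1 / sqrt(sum(rc$total[keep]))
  expect_lt(abs(rbar), 3 * se + 1e-4)
  expect_true(all(is.na(rc$r[rc$total < 10])))

  # noiseless construction: r at every usable channel equals the model
  frozen <- AnisotropyComponents(0.2, 1e7)
  pol0 <- noiselessPolarized(cmp, frozen, irf, scale = 1e7)
  rc0 <- anisotropyCurve(pol0)
  keep0 <- !is.na(rc0$r) & rc0$total > 1e4
  expect_equal(max(abs(rc0$r[keep0] - 0.2)), 0, tolerance = 1e-3)
})

test_that("r(0) equals the beta sum across seeded simulations", {
  irf <- deltaIRF(1024, 0.02)
  cmp <- DecayComponents(1, 2.5)
  an <- AnisotropyComponents(c(0.05, 0.15), c(5, 12))
  for (s in 1:10) {
    pol <- simulatePolarized(cmp, an, irf, gFactor = 1, totalCounts = 5e5,
                             seed = 300 + s)
    rc <- anisotropyCurve(pol)
    early <- which(!is.na(rc$r))[1:5]
    r0hat <- stats::weighted.mean(rc$r[early], rc$total[early])
    se <- 1.5 / sqrt(sum(rc$total[early]))
    expect_lt(abs(r0hat - 0.2), 4 * se + 0.005)
  }
})

test_that("fitAnisotropy recovers a noiseless single rotor exactly", {
  irf <- smallIRF()
  cmp <- DecayComponents(1, 2.5)
  an <- AnisotropyComponents(0.2, 5)
  pol <- noiselessPolarized(cmp, an, irf, scale = 1e7)
  f <- fitAnisotropy(pol, cmp, 1)
  expect_equal(thetas(f), 5, tolerance = 1e-6)
  expect_equal(betas(f), 0.2, tolerance = 1e-6)
})

test_that("fitAnisotropy recovers the Dre2 rotational models", {
  irf <- makeIRF(2, 0.5, 2048, 0.02)
  ref <- ntdRef()
  pol <- simulatePolarized(ref$lifetimes, ref$anisotropy, irf,
                           gFactor = 1, totalCounts = 5e6, seed = 31)
  f <- fitAnisotropy(pol, ref$lifetimes, 3, init = thetas(ref$anisotropy))
  expect_equal(max(thetas(f)), 8.6, tolerance = 0.06)  # ~0.5 ns absolute
  expect_equal(rTotal(f), 0.207, tolerance = 0.1)

  holo <- dre2Reference("fl-holo")
  pol2 <- simulatePolarized(holo$lifetimes, holo$anisotropy, irf,
                            gFactor = 1, totalCounts = 5e6, seed = 32)
  f2 <- fitAnisotropy(pol2, holo$lifetimes, 2,
                      init = thetas(holo$anisotropy))
  expect_equal(max(thetas(f2)), 17, tolerance = 0.12)
  expect_equal(rTotal(f2), 0.125, tolerance = 0.1)
})

test_that("totalAnisotropy sums the amplitudes", {
  expect_equal(totalAnisotropy(ntdRef()$anisotropy), 0.207)
  expect_equal(totalAnisotropy(dre2Reference("fl-apo")$anisotropy), 0.181)
  expect_equal(totalAnisotropy(AnisotropyComponents(numeric(0),
                                                    numeric(0))), 0)
})

test_that("coneAngle solves the wobbling-in-cone relation", {
  # closed form matches a brute-force scan of the defining relation
  bruteCone <- function(beta, r0) {
    w <- seq(0, 90, by = 1e-3) * pi / 180
    lhs <- 0.5 * cos(w) * (1 + cos(w))
    (w[which.min(abs(lhs - sqrt(beta / r0)))]) * 180 / pi
  }
  for (beta in seq(0.005, 0.185, length.out = 100))
    expect_lt(abs(coneAngle(beta, 0.185) - bruteCone(beta, 0.185)), 0.01)
  expect_equal(coneAngle(0.0925, 0.185), 37.810, tolerance = 1e-3)

  # limits and monotonicity
  expect_equal(coneAngle(0.185, 0.185), 0)
  expect_equal(coneAngle(0, 0.185), 90)
  sweep <- coneAngle(seq(0.001, 0.185, length.out = 50), 0.185)
  expect_true(all(diff(sweep) < 0))

  # the three reported slow amplitudes give the reported integer angles
  expect_equal(round(coneAngle(0.156, 0.185)), 19)
  expect_equal(round(coneAngle(0.132, 0.185)), 27)
  expect_equal(round(coneAngle(0.091, 0.185)), 38)

  expect_error(coneAngle(0.2, 0.185), "exceeds r0")
})
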