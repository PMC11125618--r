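test_that("disjoint spectra give J = 0 with a warning", {
  em <- Spectrum(300:340, exp(-(300:340 - 320) ^ 2 / 50))
  ab <- AbsorptionSpectrum(400:440, rep(0.1, 41), molarConcentration = 1e-5)
  expect_warning(J <- overlapIntegral(em, ab), "no common wavelength")
  expect_equal(J, 0)
})

test_that("flat-band overlap matches the closed form", {
  # flat F and flat eps = 1e4 on 340-341 nm: F cancels, and
  # J = eps * mean(lambda^4) with lambda in cm ~ 1.344e-14 cm^3 L / mol
  em <- Spectrum(c(340, 340.5, 341), rep(1, 3))
  ab <- AbsorptionSpectrum(c(340, 340.5, 341), rep(1e4 * 1e-5, 3),
                           molarConcentration = 1e-5)
  J <- overlapIntegral(em, ab)
  closed <- 1e4 * 1e-28 * (341 ^ 5 - 340 ^ 5) / 5  # exact integral of l^4
  expect_equal(J, closed, tolerance = 1e-4)
  expect_equal(J, 1.344e-14, tolerance = 1e-3)
})

test_that("1 nm-grid overlap integral agrees with a 0.01 nm quadrature oracle", {
  sp <- genOpticalSpectra(noiseFraction = 0)
  J <- overlapIntegral(sp$emission, sp$absorption)
  expect_equal(J, oracle_overlap(sp$emission, sp$absorption),
               tolerance = 1e-3)
})

test_that("J is invariant under uniform scaling of emission intensities", {
  sp <- genOpticalSpectra(noiseFraction = 0)
  em2 <- Spectrum(spectrumAxis(sp$emission), intensity(sp$emission) * 123.4)
  expect_equal(overlapIntegral(em2, sp$absorption),
               overlapIntegral(sp$emission, sp$absorption),
               tolerance = 1e-12)
})

test_that("zero emission over the overlap is an undefined-integral error", {
  em <- Spectrum(300:400, rep(0, 101))
  ab <- AbsorptionSpectrum(300:400, rep(0.1, 101), molarConcentration = 1e-5)
  expect_error(overlapIntegral(em, ab), "undefined")
})

test_that("Forster radius reproduces the sixth-root law and scaling", {
  expect_equal(forsterRadius(0), 0)
  J <- 3e-14
  expect_equal(forsterRadius(64 * J) / forsterRadius(J), 2,
               tolerance = 1e-12)
  expect_error(forsterRadius(-1e-14), "non-negative")
})

test_that("Forster radius is monotonic in each constant", {
  J <- 5e-14
  expect_gt(forsterRadius(J * 1.1), forsterRadius(J))
  expect_gt(forsterRadius(J, K2 = 0.8), forsterRadius(J, K2 = 2 / 3))
  expect_gt(forsterRadius(J, phi = 0.2), forsterRadius(J, phi = 0.15))
  expect_lt(forsterRadius(J, N = 1.4), forsterRadius(J, N = 1.34))
})

test_that("transfer efficiency is 1 - F/F0 with guarded domain", {
  expect_equal(transferEfficiency(100, 100), 0)
  expect_equal(transferEfficiency(0, 100), 1)
  expect_equal(transferEfficiency(82, 100), 0.18)
  expect_error(transferEfficiency(101, 100), "exceed")
  expect_error(transferEfficiency(1, 0), "positive")
})

test_that("donor-acceptor distance inverts the efficiency relation", {
  expect_equal(donorAcceptorDistance(5, 0.5), 5)  # r = R0 at 50 % transfer
  expect_equal(round(donorAcceptorDistance(4.07, 0.21), 2), 5.08)
  expect_error(donorAcceptorDistance(3, 0), "infinite")
  expect_warning(r0 <- donorAcceptorDistance(3, 1), "zero")
  expect_equal(r0, 0)
})

test_that("E and r satisfy the sixth-power identity to 10 significant digits", {
  set.seed(21)
  for (i in 1:25) {
    R0 <- runif(1, 1, 6)
    E <- runif(1, 0.02, 0.98)
    r <- donorAcceptorDistance(R0, E)
    expect_equal(E * (R0 ^ 6 + r ^ 6), R0 ^ 6, tolerance = 1e-10)
  }
})

test_that("validity requires r in [0.5 R0, 1.5 R0] and below 7 nm", {
  v <- fretValidity(4.87, 3.50)
  expect_true(v$valid)
  expect_length(v$reasons, 0)
  v2 <- fretValidity(8, 6)
  expect_false(v2$valid)
  expect_true(any(grepl("7 nm", v2$reasons)))
  v3 <- fretValidity(0.4 * 3.5, 3.5)
  expect_false(v3$valid)
  expect_true(any(grepl("0.5 R0", v3$reasons)))
  v4 <- fretValidity(1.6 * 3.5, 3.5)
  expect_true(any(grepl("1.5 R0", v4$reasons)))
})

test_that("fretAnalysis composes the chain into a consistent FretResult", {
  sp <- genOpticalSpectra(noiseFraction = 0)
  res <- fretAnalysis(sp$emission, sp$absorption, F = 870, F0 = 1000)
  expect_s4_class(res, "FretResult")
  expect_equal(res@E, 0.13)
  expect_equal(res@R0, forsterRadius(res@J), tolerance = 1e-12)
  expect_equal(res@r, donorAcceptorDistance(res@R0, res@E),
               tolerance = 1e-12)
  expect_true(res@valid)
})
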