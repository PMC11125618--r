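gauss_spec <- function(centers, amps, sigmas, baseline = c(0, 0),
                       grid = seq(1580, 1720, by = 1)) {
  y <- baseline[1] + baseline[2] * (grid - 1580)
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(grid - centers[i]) ^ 2 / (2 * sigmas[i] ^ 2))
  Spectrum(grid, y, axisKind = "wavenumber_cm-1",
           signalKind = "ftir_absorbance")
}

test_that("amide window extraction removes a linear baseline", {
  flat <- gauss_spec(numeric(), numeric(), numeric(), baseline = c(0.4, 0))
  w <- extractAmideWindow(flat)
  expect_equal(range(spectrumAxis(w)), c(1600, 1700))
  expect_true(all(intensity(w) == 0))

  sloped <- gauss_spec(1655, 0.5, 5, baseline = c(0.1, 2e-3))
  w2 <- extractAmideWindow(sloped)
  peak <- spectrumAxis(w2)[which.max(intensity(w2))]
  expect_lt(abs(peak - 1655), 0.5)
  # baseline residue at the window edges is tiny compared with the band
  expect_lt(intensity(w2)[1], 0.02 * max(intensity(w2)))
})

test_that("window extraction rejects incomplete coverage", {
  short <- Spectrum(seq(1650, 1700, 1), rep(0.1, 51),
                    axisKind = "wavenumber_cm-1",
                    signalKind = "ftir_absorbance")
  expect_error(extractAmideWindow(short), "must cover")
  gap <- Spectrum(c(seq(1580, 1620, 1), seq(1680, 1720, 1)),
                  rep(0.1, 82), axisKind = "wavenumber_cm-1",
                  signalKind = "ftir_absorbance")
  expect_error(extractAmideWindow(gap), "gap")
  optical <- Spectrum(300:450, rep(1, 151))
  expect_error(extractAmideWindow(optical), "wavenumber")
})

test_that("second-derivative detection finds band centres", {
  one <- extractAmideWindow(gauss_spec(1655, 0.5, 5))
  cand <- detectAmideBands(one)
  expect_length(cand, 1)
  expect_lt(abs(cand - 1655), 1)

  two <- extractAmideWindow(gauss_spec(c(1625, 1675), c(0.4, 0.5), c(5, 5)))
  cand2 <- detectAmideBands(two)
  expect_length(cand2, 2)
  expect_lt(abs(cand2[1] - 1625), 1)
  expect_lt(abs(cand2[2] - 1675), 1)

  zero <- extractAmideWindow(gauss_spec(numeric(), numeric(), numeric()))
  expect_length(detectAmideBands(zero), 0)
})

test_that("Gaussian band fitting recovers generating parameters", {
  w <- extractAmideWindow(gauss_spec(1655, 0.5, 5))
  b <- fitAmideBands(w, detectAmideBands(w))
  expect_equal(nrow(b), 1)
  expect_equal(b$center, 1655, tolerance = 0.01)
  expect_equal(b$sigma, 5, tolerance = 0.01)
  expect_equal(b$amplitude, 0.5, tolerance = 0.01)
  expect_lt(attr(b, "residualRMS"), 1e-3)

  # 30:70 area ratio recovered within a percentage point
  amps <- c(0.3, 0.7) / (4 * sqrt(2 * pi))
  w2 <- extractAmideWindow(gauss_spec(c(1625, 1655), amps, c(4, 4)))
  b2 <- fitAmideBands(w2, c(1625, 1655))
  frac <- 100 * b2$area / sum(b2$area)
  expect_equal(frac, c(30, 70), tolerance = 0.04)

  # zero-signal window: all amplitudes zero
  wz <- extractAmideWindow(gauss_spec(numeric(), numeric(), numeric()))
  bz <- fitAmideBands(wz, c(1630, 1660))
  expect_equal(bz$amplitude, c(0, 0))
  expect_error(fitAmideBands(wz, numeric()), "at least one")
})

test_that("assignment windows are half-open with ties going upward", {
  centers <- c(1605, 1610, 1625, 1639.9, 1640, 1649.9, 1650, 1655,
               1660, 1671, 1680, 1685, 1692, 1695)
  expected <- c("unassigned", "beta_sheet", "beta_sheet", "beta_sheet",
                "random_coil", "random_coil", "alpha_helix", "alpha_helix",
                "beta_turn", "beta_turn", "beta_antiparallel",
                "beta_antiparallel", "beta_antiparallel", "unassigned")
  b <- data.frame(center = centers, sigma = 4, amplitude = 1)
  b$area <- b$amplitude * b$sigma * sqrt(2 * pi)
  res <- assignSecondaryStructure(b)
  expect_equal(unname(amideBands(res)$assignment), expected)
})

test_that("percentages are areas over the assigned base", {
  b <- data.frame(center = c(1625, 1655), sigma = c(5, 5),
                  amplitude = c(30, 70) / (5 * sqrt(2 * pi)))
  b$area <- b$amplitude * b$sigma * sqrt(2 * pi)
  pct <- structurePercent(assignSecondaryStructure(b))
  expect_equal(unname(pct["beta_sheet"]), 30, tolerance = 1e-9)
  expect_equal(unname(pct["alpha_helix"]), 70, tolerance = 1e-9)

  # single band at 1685 is pure antiparallel beta
  b2 <- data.frame(center = 1685, sigma = 5, amplitude = 1)
  b2$area <- b2$amplitude * b2$sigma * sqrt(2 * pi)
  pct2 <- structurePercent(assignSecondaryStructure(b2))
  expect_equal(unname(pct2["beta_antiparallel"]), 100)

  # unassigned bands are excluded from the base
  b3 <- rbind(b, data.frame(center = 1695, sigma = 5, amplitude = 10,
                            area = 10 * 5 * sqrt(2 * pi)))
  pct3 <- structurePercent(assignSecondaryStructure(b3))
  expect_equal(unname(pct3["beta_sheet"]), 30, tolerance = 1e-9)

  # zero assigned area is an undefined composition
  b4 <- data.frame(center = 1695, sigma = 5, amplitude = 1)
  b4$area <- b4$amplitude * b4$sigma * sqrt(2 * pi)
  expect_error(assignSecondaryStructure(b4), "undefined")
})

test_that("end-to-end pipeline recovers known compositions", {
  sp <- genAmideComposite(fractions = c(0, 0, 1, 0, 0), noiseFraction = 0)
  pct <- structurePercent(ftirSecondaryStructure(sp))
  expect_equal(unname(pct["alpha_helix"]), 100, tolerance = 1e-6)

  sp2 <- genAmideComposite(fractions = c(0.3, 0, 0.7, 0, 0),
                           noiseFraction = 0)
  pct2 <- structurePercent(ftirSecondaryStructure(sp2))
  expect_equal(unname(pct2["beta_sheet"]), 30, tolerance = 0.7)
  expect_equal(unname(pct2["alpha_helix"]), 70, tolerance = 0.7)
})

test_that("percentages always sum to 100 and the pipeline is deterministic", {
  for (s in 1:5) {
    set.seed(s)
    f <- runif(5); f <- f / sum(f)
    sp <- genAmideComposite(fractions = f, noiseFraction = 0.005, seed = s)
    pct <- structurePercent(ftirSecondaryStructure(sp))
    expect_equal(sum(pct), 100, tolerance = 1e-3)
  }
  sp <- genAmideComposite(fractions = c(0.2, 0.2, 0.2, 0.2, 0.2),
                          noiseFraction = 0.005, seed = 4)
  r1 <- ftirSecondaryStructure(sp)
  r2 <- ftirSecondaryStructure(sp)
  expect_identical(structurePercent(r1), structurePercent(r2))
})
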