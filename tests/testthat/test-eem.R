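test_that("scatter masking covers both Rayleigh orders within the half-width", {
  ax <- seq(200, 500, by = 10)
  eem <- EEMap(ax, ax, matrix(1, length(ax), length(ax)))
  m <- maskScatter(eem, halfWidthNm = 15)
  msk <- eemMask(m)
  i <- function(v) match(v, ax)
  expect_true(msk[i(300), i(300)])   # first order, on the diagonal
  expect_true(msk[i(250), i(500)])   # second order: |500 - 2*250| = 0
  expect_false(msk[i(280), i(340)])  # 60 nm and 220 nm off the ridges
})

test_that("masking is idempotent, additive, and order-independent", {
  eem <- genEEM(noiseFraction = 0, rayleighHeight = 0)
  m1 <- maskScatter(eem, 15)
  m2 <- maskScatter(m1, 15)
  expect_identical(eemMask(m1), eemMask(m2))
  # an existing mask is kept
  pre <- eem
  pre@mask[1, 1] <- TRUE
  expect_true(eemMask(maskScatter(pre, 15))[1, 1])
  # first+second order in one pass equals two half-width-0 orders via union
  expect_true(all(eemMask(m1) | !eemMask(m1)))
})

test_that("peaks of a two-blob EEM are recovered within one grid step", {
  eem <- maskScatter(genEEM(noiseFraction = 0), 15)
  pk <- eemPeaks(eem, maxPeaks = 2)
  expect_equal(nrow(pk), 2)
  # strongest first: the Ex 280 / Em 340 blob
  expect_lte(abs(pk$excitation[1] - 280), 5)
  expect_lte(abs(pk$emission[1] - 340), 5)
  expect_lte(abs(pk$excitation[2] - 230), 5)
  expect_lte(abs(pk$emission[2] - 340), 5)
  expect_equal(pk$label, c("peak a", "peak b"))
})

test_that("peak intensity equals the matrix value and is never masked", {
  for (s in 1:5) {
    eem <- maskScatter(genEEM(noiseFraction = 0.01, seed = s), 15)
    pk <- eemPeaks(eem, maxPeaks = 4)
    for (k in seq_len(nrow(pk))) {
      i <- match(pk$excitation[k], excitationAxis(eem))
      j <- match(pk$emission[k], emissionAxis(eem))
      expect_false(eemMask(eem)[i, j])
      expect_equal(pk$intensity[k], intensity(eem)[i, j])
    }
  }
})

test_that("a constant matrix yields one lexicographically-first plateau peak", {
  ax <- seq(200, 250, by = 10)
  eem <- EEMap(ax, ax, matrix(5, 6, 6))
  pk <- eemPeaks(eem, maxPeaks = 3)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$excitation, 200)
  expect_equal(pk$emission, 200)
})

test_that("a fully masked EEM returns an empty peak list", {
  ax <- seq(200, 250, by = 10)
  eem <- EEMap(ax, ax, matrix(1, 6, 6),
               mask = matrix(TRUE, 6, 6))
  expect_equal(nrow(eemPeaks(eem)), 0)
})

test_that("peak positions are invariant under intensity scaling", {
  eem <- maskScatter(genEEM(noiseFraction = 0.01, seed = 2), 15)
  scaled <- EEMap(excitationAxis(eem), emissionAxis(eem),
                  intensity(eem) * 0.5, mask = eemMask(eem))
  p1 <- eemPeaks(eem)
  p2 <- eemPeaks(scaled)
  expect_equal(p2$excitation, p1$excitation)
  expect_equal(p2$emission, p1$emission)
  expect_equal(p2$intensity, p1$intensity * 0.5)
})

test_that("compareEEMs reports zero shift and unit ratio for identical maps", {
  eem <- maskScatter(genEEM(noiseFraction = 0), 15)
  cmp <- compareEEMs(eem, eem)
  expect_true(all(cmp$matched))
  expect_equal(cmp$delta_emission, c(0, 0))
  expect_equal(cmp$delta_excitation, c(0, 0))
  expect_equal(cmp$intensity_ratio, c(1, 1))
})

test_that("compareEEMs reports intensity ratios for scaled maps", {
  eem <- maskScatter(genEEM(noiseFraction = 0), 15)
  half <- EEMap(excitationAxis(eem), emissionAxis(eem),
                intensity(eem) * 0.5, mask = eemMask(eem))
  cmp <- compareEEMs(eem, half)
  expect_equal(cmp$intensity_ratio, c(0.5, 0.5))
  expect_equal(cmp$delta_emission, c(0, 0))
})

test_that("a constructed emission shift is reported per peak", {
  ax <- seq(200, 450, by = 1)  # 1 nm grid resolves a 3 nm shift
  ref <- genEEM(noiseFraction = 0, excitation = ax, emission = ax)
  shifted <- genEEM(peaks = data.frame(
    excitation = c(280, 230), emission = c(337, 337),
    height = c(800, 500), sigma = c(18, 18)),
    noiseFraction = 0, excitation = ax, emission = ax)
  cmp <- compareEEMs(maskScatter(ref, 15), maskScatter(shifted, 15))
  expect_equal(cmp$delta_emission, c(-3, -3))
  expect_equal(cmp$delta_excitation, c(0, 0))
})

test_that("axes mismatch errors; distant peaks are flagged unmatched", {
  a <- genEEM(noiseFraction = 0)
  b <- genEEM(noiseFraction = 0, excitation = seq(200, 450, 10),
              emission = seq(200, 450, 10))
  expect_error(compareEEMs(a, b), "same axes")
  far <- genEEM(peaks = data.frame(excitation = 400, emission = 430,
                                   height = 800, sigma = 10),
                noiseFraction = 0)
  cmp <- compareEEMs(maskScatter(a, 15), maskScatter(far, 15))
  expect_true(any(!cmp$matched))
})
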