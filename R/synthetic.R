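# Synthetic-data generators with known ground truth for every input class.
# Each generator is a deterministic function of its arguments including the
# seed; noise is multiplicative Gaussian on intensities (photodetector noise
# scales with signal).

#' Generate a static-quenching titration with known Ka and n
#'
#' Forward model F = F0 / (1 + Ka [Q]^n), the exact inverse of the
#' double-logarithm binding model, so [fitDoubleLog()] recovers (Ka, n)
#' exactly at zero noise. Multiplicative Gaussian noise is applied at
#' nonzero concentrations only (the reference F0 stays exact).
#'
#' @param Ka apparent binding constant, L/mol (> 0). Default 2e6, a typical
#'   strong protein-ligand affinity.
#' @param n binding-site number (> 0).
#' @param F0 unquenched intensity.
#' @param concentrations quencher concentrations, mol/L, starting at 0.
#'   Default 0-9 x 1e-7 M, a standard ten-step titration grid.
#' @param temperatureK temperature, K.
#' @param noiseFraction relative s.d. of the multiplicative noise
#'   (default 0.01).
#' @param seed RNG seed; same seed, same series.
#' @return A [TitrationSeries-class].
#' @examples
#' ts <- genTitration(Ka = 2e6, n = 1, noiseFraction = 0)
#' fitDoubleLog(ts)
#' @export
genTitration <- function(Ka = 2e6, n = 1, F0 = 1000,
                         concentrations = (0:9) * 1e-7, temperatureK = 298,
                         noiseFraction = 0.01, seed = 1) {
  stopifnot(Ka > 0, n > 0, F0 > 0, noiseFraction >= 0)
  q <- as.numeric(concentrations)
  if (!length(q) || q[1L] != 0)
    stop("'concentrations' must start at 0", call. = FALSE)
  f <- F0 / (1 + Ka * q ^ n)
  if (noiseFraction > 0) {
    nz <- which(q > 0)
    f[nz] <- .withSeed(seed,
      f[nz] * (1 + stats::rnorm(length(nz), 0, noiseFraction)))
    f <- pmax(f, 1e-9 * F0)
  }
  TitrationSeries(q, f, temperatureK = temperatureK)
}

#' Generate overlapping Gaussian emission and absorption spectra
#'
#' Emulates a tryptophan-like protein emission band (Gaussian, peak near
#' 340 nm) and a ligand UV absorption band on the 300-450 nm range. The
#' default band parameters were calibrated once, against a fine-grid
#' quadrature of the overlap integral, to give J near 6.7e-14 cm^3 L / mol
#' with the default constants, i.e. a Forster radius near 3.5 nm.
#'
#' @param emissionCenterNm,emissionSigmaNm emission band centre and
#'   Gaussian sigma, nm.
#' @param absorptionCenterNm,absorptionSigmaNm absorption band centre and
#'   sigma, nm.
#' @param epsilonMax peak molar absorptivity, L/mol/cm.
#' @param emissionMax peak emission intensity (arbitrary units; J is
#'   invariant to it).
#' @param molarConcentration absorber concentration, mol/L.
#' @param pathLengthCm optical path, cm.
#' @param rangeNm two-element wavelength range, nm.
#' @param stepNm grid step, nm.
#' @param noiseFraction relative multiplicative noise s.d. (default 0.01).
#' @param seed RNG seed.
#' @return A list with elements `emission` ([Spectrum-class]) and
#'   `absorption` ([AbsorptionSpectrum-class]).
#' @export
genOpticalSpectra <- function(emissionCenterNm = 340, emissionSigmaNm = 20,
                              absorptionCenterNm = 345,
                              absorptionSigmaNm = 40, epsilonMax = 5.45e4,
                              emissionMax = 1000, molarConcentration = 1e-5,
                              pathLengthCm = 1, rangeNm = c(300, 450),
                              stepNm = 1, noiseFraction = 0.01, seed = 1) {
  stopifnot(emissionSigmaNm > 0, absorptionSigmaNm > 0, epsilonMax >= 0,
            noiseFraction >= 0)
  grid <- seq(rangeNm[1L], rangeNm[2L], by = stepNm)
  fem <- emissionMax * exp(-(grid - emissionCenterNm) ^ 2 /
                             (2 * emissionSigmaNm ^ 2))
  abs0 <- epsilonMax * molarConcentration * pathLengthCm *
    exp(-(grid - absorptionCenterNm) ^ 2 / (2 * absorptionSigmaNm ^ 2))
  if (noiseFraction > 0) {
    noise <- .withSeed(seed, list(
      em = stats::rnorm(length(grid), 0, noiseFraction),
      ab = stats::rnorm(length(grid), 0, noiseFraction)))
    fem <- pmax(fem * (1 + noise$em), 0)
    abs0 <- pmax(abs0 * (1 + noise$ab), 0)
  }
  list(
    emission = Spectrum(grid, fem, axisKind = "wavelength_nm",
                        signalKind = "fluorescence_emission",
                        label = "synthetic emission"),
    absorption = AbsorptionSpectrum(grid, abs0,
                                    molarConcentration = molarConcentration,
                                    pathLengthCm = pathLengthCm,
                                    label = "synthetic absorption"))
}

.AMIDE_DEFAULT_CENTERS <- c(beta_sheet = 1628, random_coil = 1645,
                            alpha_helix = 1655, beta_turn = 1671,
                            beta_antiparallel = 1686)

#' Generate a synthetic amide-I composite spectrum
#'
#' Sum of one Gaussian band per secondary-structure class with band areas
#' proportional to the requested fractions, on 1580-1720 cm^-1 at 1 cm^-1
#' steps, plus an optional linear baseline and multiplicative noise.
#' Default centres sit at typical literature positions inside each
#' assignment window; a centre outside its class window is an error.
#'
#' @param fractions length-5 non-negative vector summing to 1, ordered
#'   (beta_sheet, random_coil, alpha_helix, beta_turn, beta_antiparallel).
#' @param centers band centres, cm^-1, each inside its class window.
#' @param sigmas Gaussian sigmas, cm^-1.
#' @param totalArea total band area (absorbance x cm^-1).
#' @param baseline length-2 numeric `(offset, slope)` of a linear baseline
#'   added to the composite (slope per cm^-1 relative to 1580).
#' @param noiseFraction relative multiplicative noise s.d. (default 0.01).
#' @param seed RNG seed.
#' @return An FTIR [Spectrum-class]; the generating band table is attached
#'   as attribute `"truth"`.
#' @examples
#' sp <- genAmideComposite(fractions = c(0.3, 0, 0.7, 0, 0),
#'                         noiseFraction = 0)
#' structurePercent(ftirSecondaryStructure(sp))
#' @export
genAmideComposite <- function(fractions,
                              centers = .AMIDE_DEFAULT_CENTERS,
                              sigmas = rep(4, 5), totalArea = 10,
                              baseline = c(0.02, 1e-4),
                              noiseFraction = 0.01, seed = 1) {
  if (length(fractions) != 5L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be 5 non-negative values summing to 1",
         call. = FALSE)
  if (length(centers) != 5L || length(sigmas) != 5L || any(sigmas <= 0))
    stop("'centers' and 'sigmas' must have length 5, sigmas positive",
         call. = FALSE)
  cls <- names(.AMIDE_DEFAULT_CENTERS)
  assigned <- .assignCenter(centers)
  bad <- which(assigned != cls & fractions > 0)
  if (length(bad))
    stop(sprintf("center %g cm^-1 is outside the %s window",
                 centers[bad[1L]], cls[bad[1L]]), call. = FALSE)
  grid <- seq(1580, 1720, by = 1)
  areas <- totalArea * fractions
  amp <- areas / (sigmas * sqrt(2 * pi))
  y <- numeric(length(grid))
  for (i in 1:5)
    y <- y + amp[i] * exp(-(grid - centers[i]) ^ 2 / (2 * sigmas[i] ^ 2))
  y <- y + baseline[1L] + baseline[2L] * (grid - 1580)
  if (noiseFraction > 0)
    y <- .withSeed(seed, y * (1 + stats::rnorm(length(grid), 0,
                                               noiseFraction)))
  sp <- Spectrum(grid, y, axisKind = "wavenumber_cm-1",
                 signalKind = "ftir_absorbance",
                 label = "synthetic amide-I composite")
  attr(sp, "truth") <- data.frame(class = cls, center = unname(centers),
                                  sigma = sigmas, area = areas,
                                  fraction = fractions,
                                  stringsAsFactors = FALSE)
  sp
}

#' Generate a synthetic EEM with fluorescence peaks and a Rayleigh ridge
#'
#' Sum of 2-D Gaussian fluorescence blobs plus a first-order Rayleigh
#' scatter ridge along emission = excitation. Returned unmasked; apply
#' [maskScatter()] before peak analysis. Defaults emulate the two protein
#' peaks (peak a near Ex 230 / Em 340, peak b near Ex 280 / Em 340) on a
#' 200-450 nm grid with a 5 nm increment.
#'
#' @param peaks data.frame with columns `excitation`, `emission`, `height`,
#'   `sigma` (nm), one row per fluorescence peak, all inside the axes.
#' @param rayleighHeight peak height of the scatter ridge.
#' @param rayleighSigmaNm Gaussian half-width of the ridge, nm.
#' @param excitation,emission axes, nm.
#' @param noiseFraction relative multiplicative noise s.d. (default 0.01).
#' @param seed RNG seed.
#' @return An [EEMap-class] (mask all `FALSE`).
#' @examples
#' eem <- maskScatter(genEEM(noiseFraction = 0))
#' eemPeaks(eem)
#' @export
genEEM <- function(peaks = data.frame(
                     excitation = c(280, 230), emission = c(340, 340),
                     height = c(800, 500), sigma = c(18, 18)),
                   rayleighHeight = 1000, rayleighSigmaNm = 6,
                   excitation = seq(200, 450, by = 5),
                   emission = seq(200, 450, by = 5),
                   noiseFraction = 0.01, seed = 1) {
  stopifnot(is.data.frame(peaks), noiseFraction >= 0)
  if (nrow(peaks)) {
    if (any(peaks$excitation < min(excitation) |
            peaks$excitation > max(excitation) |
            peaks$emission < min(emission) |
            peaks$emission > max(emission)))
      stop("peak positions must lie inside the axes", call. = FALSE)
  }
  m <- matrix(0, length(excitation), length(emission))
  for (i in seq_len(nrow(peaks))) {
    m <- m + peaks$height[i] *
      outer(exp(-(excitation - peaks$excitation[i]) ^ 2 /
                  (2 * peaks$sigma[i] ^ 2)),
            exp(-(emission - peaks$emission[i]) ^ 2 /
                  (2 * peaks$sigma[i] ^ 2)))
  }
  if (rayleighHeight > 0)
    m <- m + rayleighHeight *
      exp(-outer(excitation, emission, function(x, mm) (mm - x) ^ 2) /
            (2 * rayleighSigmaNm ^ 2))
  if (noiseFraction > 0)
    m <- .withSeed(seed,
                   m * (1 + matrix(stats::rnorm(length(m), 0, noiseFraction),
                                   nrow(m), ncol(m))))
  EEMap(excitation, emission, m)
}
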