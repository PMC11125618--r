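# Forster resonance energy transfer: overlap integral, Forster radius,
# transfer efficiency, donor-acceptor distance, validity conditions.
#
#   J   = sum F(l) eps(l) l^4 dl / sum F(l) dl   (l in cm, eps in L/mol/cm)
#   R0^6 = 8.8e-25 K^2 N^-4 Phi J                 (R0 in cm)
#   E   = 1 - F/F0 = R0^6 / (R0^6 + r^6)
#
# The 8.8e-25 prefactor presumes the wavelength inside the overlap integral
# is expressed in cm; with J then in cm^3 L / mol, R0 comes out in cm.

# Trapezoidal integral on a possibly non-uniform grid.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Spectral overlap integral J
#'
#' Normalised overlap of the donor emission spectrum with the acceptor molar
#' absorptivity, weighted by the fourth power of the wavelength. Both curves
#' are linearly interpolated onto a shared 1 nm grid over their common
#' wavelength interval and integrated with trapezoidal weights; the
#' wavelength enters in cm, so J carries units of cm^3 L / mol. J is
#' invariant under uniform scaling of the emission intensities (F appears in
#' numerator and denominator).
#'
#' @param emission donor emission [Spectrum-class] (wavelength in nm).
#' @param absorption acceptor [AbsorptionSpectrum-class]; its absorbance is
#'   converted to molar absorptivity via Beer-Lambert.
#' @return J in cm^3 L / mol. Disjoint spectra give `0` with a warning.
#' @examples
#' sp <- genOpticalSpectra()
#' overlapIntegral(sp$emission, sp$absorption)
#' @export
overlapIntegral <- function(emission, absorption) {
  stopifnot(is(emission, "Spectrum"), is(absorption, "AbsorptionSpectrum"))
  if (emission@axisKind != "wavelength_nm" ||
      absorption@axisKind != "wavelength_nm")
    stop("both spectra must be on a wavelength (nm) axis", call. = FALSE)
  lo <- max(min(emission@axis), min(absorption@axis))
  hi <- min(max(emission@axis), max(absorption@axis))
  if (hi <= lo) {
    warning("emission and absorption spectra have no common wavelength ",
            "support; J = 0", call. = FALSE)
    return(0)
  }
  grid <- seq(lo, hi, by = 1)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  if (length(grid) < 2L) grid <- c(lo, hi)
  Fv <- stats::approx(emission@axis, emission@intensity, xout = grid)$y
  eps <- stats::approx(absorption@axis, molarAbsorptivity(absorption),
                       xout = grid)$y
  denom <- .trapz(grid, Fv)
  if (denom <= 0)
    stop("total emission intensity over the overlap interval is zero; ",
         "the overlap integral is undefined", call. = FALSE)
  lam_cm <- grid * 1e-7
  .trapz(grid, Fv * eps * lam_cm ^ 4) / denom
}

#' Forster radius from the overlap integral
#'
#' R0 = (8.8e-25 K^2 N^-4 Phi J)^(1/6) in cm, returned in nm. R0 is the
#' donor-acceptor distance at which the transfer efficiency is 50 %.
#'
#' @param J overlap integral, cm^3 L / mol (>= 0).
#' @param K2 dipole orientation factor; 2/3 for freely rotating dipoles.
#' @param N refractive index of the medium; ~1.34 for water/biomolecule
#'   mixtures.
#' @param phi donor fluorescence quantum yield; ~0.15 for intrinsic protein
#'   fluorescence.
#' @return R0 in nm.
#' @examples
#' forsterRadius(6.70e-14)  # 3.50 nm
#' @export
forsterRadius <- function(J, K2 = 2 / 3, N = 1.34, phi = 0.15) {
  .assertScalarNumber(J, "J")
  .assertScalarNumber(K2, "K2")
  .assertScalarNumber(N, "N")
  .assertScalarNumber(phi, "phi")
  if (J < 0) stop("'J' must be non-negative", call. = FALSE)
  if (N <= 0) stop("'N' must be positive", call. = FALSE)
  if (phi <= 0 || phi > 1) stop("'phi' must lie in (0, 1]", call. = FALSE)
  (8.8e-25 * K2 * N ^ -4 * phi * J) ^ (1 / 6) * 1e7
}

#' Energy-transfer efficiency from intensities
#'
#' E = 1 - F/F0, with F the donor intensity at a 1:1 donor:acceptor molar
#' ratio and F0 the unquenched donor intensity.
#'
#' @param F donor intensity with acceptor present (0 <= F <= F0).
#' @param F0 unquenched donor intensity (> 0).
#' @return E in `[0, 1]`.
#' @export
transferEfficiency <- function(F, F0) {
  .assertScalarNumber(F, "F")
  .assertScalarNumber(F0, "F0")
  if (F0 <= 0) stop("'F0' must be positive", call. = FALSE)
  if (F < 0) stop("'F' must be non-negative", call. = FALSE)
  if (F > F0)
    stop("'F' must not exceed 'F0' (negative efficiency is not meaningful)",
         call. = FALSE)
  1 - F / F0
}

#' Donor-acceptor distance from R0 and E
#'
#' Inverts E = R0^6 / (R0^6 + r^6): r = R0 ((1 - E)/E)^(1/6).
#'
#' @param R0 Forster radius, nm (> 0).
#' @param E transfer efficiency, strictly between 0 and 1 (E = 1 returns
#'   r = 0 with a warning; E = 0 implies infinite distance and is an error).
#' @return r in nm.
#' @examples
#' donorAcceptorDistance(3.44, 0.18)  # 4.43 nm
#' donorAcceptorDistance(5, 0.5)      # r == R0 at 50 % efficiency
#' @export
donorAcceptorDistance <- function(R0, E) {
  .assertScalarNumber(R0, "R0")
  .assertScalarNumber(E, "E")
  if (R0 <= 0) stop("'R0' must be positive", call. = FALSE)
  if (E < 0 || E > 1) stop("'E' must lie in [0, 1]", call. = FALSE)
  if (E == 0)
    stop("E = 0 implies an infinite donor-acceptor distance", call. = FALSE)
  if (E == 1) {
    warning("E = 1 implies zero donor-acceptor distance", call. = FALSE)
    return(0)
  }
  R0 * ((1 - E) / E) ^ (1 / 6)
}

#' Energy-transfer validity conditions
#'
#' Non-radiative energy transfer is considered established when the
#' donor-acceptor distance lies within 0.5 R0 to 1.5 R0 and below 7 nm.
#'
#' @param r donor-acceptor distance, nm (> 0).
#' @param R0 Forster radius, nm (> 0).
#' @return A list with `valid` (logical) and `reasons` (character vector of
#'   violated conditions, empty when valid).
#' @examples
#' fretValidity(4.87, 3.50)
#' @export
fretValidity <- function(r, R0) {
  .assertScalarNumber(r, "r")
  .assertScalarNumber(R0, "R0")
  if (r <= 0 || R0 <= 0)
    stop("'r' and 'R0' must be positive", call. = FALSE)
  reasons <- character()
  if (r < 0.5 * R0) reasons <- c(reasons, "r below 0.5 R0")
  if (r > 1.5 * R0) reasons <- c(reasons, "r above 1.5 R0")
  if (r >= 7) reasons <- c(reasons, "r >= 7 nm")
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Complete FRET analysis
#'
#' Composes [overlapIntegral()], [forsterRadius()], [transferEfficiency()],
#' [donorAcceptorDistance()] and [fretValidity()] into one
#' [FretResult-class].
#'
#' @inheritParams overlapIntegral
#' @inheritParams transferEfficiency
#' @inheritParams forsterRadius
#' @return A [FretResult-class].
#' @export
fretAnalysis <- function(emission, absorption, F, F0, K2 = 2 / 3, N = 1.34,
                         phi = 0.15) {
  J <- overlapIntegral(emission, absorption)
  R0 <- forsterRadius(J, K2 = K2, N = N, phi = phi)
  E <- transferEfficiency(F, F0)
  r <- donorAcceptorDistance(R0, E)
  v <- if (r > 0) fretValidity(r, R0) else
    list(valid = FALSE, reasons = "r = 0 (complete quenching)")
  new("FretResult", J = J, R0 = R0, E = E, r = r, K2 = K2, N = N, phi = phi,
      valid = v$valid, reasons = v$reasons)
}
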