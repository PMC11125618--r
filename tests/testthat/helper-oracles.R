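# Independent oracles and small fixture builders used across the tests.

# Brute-force overlap-integral quadrature on a 0.01 nm grid (rectangle
# sums, wavelength in cm). Deliberately independent of the package's
# 1 nm trapezoid implementation.
oracle_overlap <- function(emission, absorption, step = 0.01) {
  ax_e <- spectrumAxis(emission)
  ax_a <- spectrumAxis(absorption)
  lo <- max(min(ax_e), min(ax_a))
  hi <- min(max(ax_e), max(ax_a))
  grid <- seq(lo, hi, by = step)
  Fv <- stats::approx(ax_e, intensity(emission), xout = grid)$y
  eps <- stats::approx(ax_a, molarAbsorptivity(absorption), xout = grid)$y
  sum(Fv * eps * (grid * 1e-7) ^ 4 * step) / sum(Fv * step)
}

# Closed-form OLS slope/intercept, written out from the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x)) ^ 2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# A clean titration following F = F0 / (1 + Ka [Q]^n), built directly.
make_titration <- function(Ka, n = 1, F0 = 1000, q = (0:9) * 1e-7,
                           temperatureK = 298) {
  TitrationSeries(q, F0 / (1 + Ka * q ^ n), temperatureK = temperatureK)
}
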