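# Stern-Volmer and double-logarithm quenching analysis.
#
# F0/F = 1 + Ksv [Q] = 1 + Kq tau0 [Q]          (Stern-Volmer)
# log10((F0 - F)/F) = log10 Ka + n log10 [Q]    (double-logarithm model)
#
# Kq above the diffusion-limited maximum of 2e10 L/mol/s diagnoses static
# quenching (ground-state complex formation).

.KQ_DYNAMIC_MAX <- 2e10

#' Fit the Stern-Volmer quenching line
#'
#' Ordinary least squares of F0/F against quencher concentration. The slope
#' is the Stern-Volmer constant Ksv; the bimolecular quenching rate constant
#' is Kq = Ksv / tau0. The intercept is left free rather than constrained to
#' its theoretical value of 1: a deviation beyond 5 % is flagged in the
#' result's notes as likely instrument drift. Constant intensities are not
#' an error; they yield Ksv = 0.
#'
#' @param series a [TitrationSeries-class] with at least 3 nonzero
#'   concentrations.
#' @param tau0 intrinsic (unquenched) fluorophore lifetime in seconds;
#'   default `1e-8`, the typical magnitude for intrinsic protein
#'   fluorescence.
#' @return A [QuenchingResult-class] with `Ksv`, `Kq`, `interceptSV`,
#'   `rSquaredSV` and `mechanism` populated (`Ka`, `n` are `NA`).
#' @examples
#' ts <- genTitration(Ka = 2e6, n = 1, noiseFraction = 0)
#' fitSternVolmer(ts)
#' @export
fitSternVolmer <- function(series, tau0 = 1e-8) {
  stopifnot(is(series, "TitrationSeries"))
  .assertScalarNumber(tau0, "tau0")
  if (tau0 <= 0) stop("'tau0' must be positive", call. = FALSE)
  q <- series@concentrations
  f <- series@intensities
  if (sum(q > 0) < 3L)
    stop("need at least 3 nonzero-concentration points", call. = FALSE)
  ratio <- f[1L] / f
  fit <- if (all(ratio == ratio[1L])) {
    # no quenching: report a flat line exactly rather than float dust
    list(intercept = ratio[1L], slope = 0, r.squared = 1)
  } else .ols(q, ratio)
  Ksv <- fit$slope
  notes <- character()
  if (abs(fit$intercept - 1) > 0.05)
    notes <- c(notes, sprintf(
      "Stern-Volmer intercept %.4g deviates from 1 by more than 5%%",
      fit$intercept))
  Kq <- Ksv / tau0
  mech <- if (Kq >= 0) classifyMechanism(Kq) else NA_character_
  new("QuenchingResult", Ksv = Ksv, Kq = Kq, tau0 = tau0,
      interceptSV = fit$intercept, rSquaredSV = fit$r.squared,
      mechanism = mech, temperatureK = series@temperatureK, notes = notes)
}

#' Classify the quenching mechanism from Kq
#'
#' Static quenching (ground-state complex) is diagnosed when the bimolecular
#' quenching rate constant strictly exceeds the maximum diffusion-limited
#' (dynamic) value of 2e10 L/mol/s; otherwise the quenching is consistent
#' with a dynamic (collisional) mechanism.
#'
#' @param Kq bimolecular quenching rate constant, L/mol/s, non-negative.
#' @return `"static"` or `"dynamic"`.
#' @examples
#' classifyMechanism(1e14)  # static
#' classifyMechanism(2e10)  # boundary: dynamic (strict inequality)
#' @export
classifyMechanism <- function(Kq) {
  .assertScalarNumber(Kq, "Kq")
  if (Kq < 0) stop("'Kq' must be non-negative", call. = FALSE)
  if (Kq > .KQ_DYNAMIC_MAX) "static" else "dynamic"
}

#' Fit the double-logarithm binding model
#'
#' Ordinary least squares of log10((F0 - F)/F) on log10([Q]) over the
#' nonzero-concentration points. The slope is the binding-site number n and
#' the apparent binding constant is Ka = 10^intercept. Points with F >= F0
#' (no net quenching; the logarithm is undefined) are dropped with a note
#' rather than clamped, which would bias the slope.
#'
#' @param series a [TitrationSeries-class].
#' @return A [QuenchingResult-class] with `Ka`, `n` and `rSquaredDL`
#'   populated.
#' @examples
#' ts <- genTitration(Ka = 2e6, n = 1, noiseFraction = 0)
#' fitDoubleLog(ts)
#' @export
fitDoubleLog <- function(series) {
  stopifnot(is(series, "TitrationSeries"))
  q <- series@concentrations
  f <- series@intensities
  f0 <- f[1L]
  nz <- which(q > 0)
  usable <- nz[f[nz] < f0]
  notes <- character()
  if (length(usable) < length(nz)) {
    dropped <- setdiff(nz, usable)
    notes <- c(notes, sprintf(
      "%d point(s) with F >= F0 dropped from the double-log fit ([Q] = %s)",
      length(dropped), paste(signif(q[dropped], 4), collapse = ", ")))
    warning(notes[length(notes)], call. = FALSE)
  }
  if (length(usable) < 3L)
    stop("fewer than 3 usable points (F < F0 at [Q] > 0) for the ",
         "double-log fit", call. = FALSE)
  x <- log10(q[usable])
  y <- log10((f0 - f[usable]) / f[usable])
  fit <- .ols(x, y)
  new("QuenchingResult", Ka = 10 ^ fit$intercept, n = fit$slope,
      rSquaredDL = fit$r.squared, temperatureK = series@temperatureK,
      notes = notes)
}

#' Full quenching analysis of one titration
#'
#' Runs [fitSternVolmer()] and [fitDoubleLog()] on the same series and
#' merges the results into a single [QuenchingResult-class].
#'
#' @inheritParams fitSternVolmer
#' @return A fully populated [QuenchingResult-class].
#' @export
quenchingAnalysis <- function(series, tau0 = 1e-8) {
  sv <- fitSternVolmer(series, tau0 = tau0)
  dl <- fitDoubleLog(series)
  new("QuenchingResult", Ksv = sv@Ksv, Kq = sv@Kq, tau0 = sv@tau0,
      Ka = dl@Ka, n = dl@n, interceptSV = sv@interceptSV,
      rSquaredSV = sv@rSquaredSV, rSquaredDL = dl@rSquaredDL,
      mechanism = sv@mechanism, temperatureK = series@temperatureK,
      notes = c(sv@notes, dl@notes))
}
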