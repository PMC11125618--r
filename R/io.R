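# Plain-text readers and writers for spectra, titrations and EEMs.
#
# All formats are delimited text: comma is tried first, then whitespace, so
# typical instrument exports load without a format flag. Values are written
# back with 17 significant digits so a write/read round trip is lossless to
# well beyond 12 significant digits.

.splitFields <- function(line) {
  line <- trimws(line)
  if (grepl(",", line, fixed = TRUE)) {
    trimws(strsplit(line, ",", fixed = TRUE)[[1L]])
  } else {
    strsplit(line, "[[:space:]]+")[[1L]]
  }
}

# Parse a two-column numeric file; returns a 2-column matrix.
# An optional single header line (non-numeric) is skipped.
.readTwoColumn <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^[[:space:]]*#", lines)
  idx <- which(keep)
  if (!length(idx))
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  first <- .splitFields(lines[idx[1L]])
  start <- 1L
  if (anyNA(suppressWarnings(as.numeric(first))))
    start <- 2L  # header row
  if (length(idx) < start)
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  rows <- lapply(idx[start:length(idx)], function(i) {
    f <- .splitFields(lines[i])
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 2L || anyNA(v))
      stop(sprintf("cannot parse two numeric columns at line %d of %s: '%s'",
                   i, path, lines[i]), call. = FALSE)
    v
  })
  do.call(rbind, rows)
}

#' Read a spectrum from a two-column text file
#'
#' Reads a comma- or whitespace-delimited file of (axis, intensity) pairs,
#' with an optional single header line. Rows are sorted by axis value and
#' duplicate axis values are collapsed to their mean intensity (repeated
#' scans are common; the mean is unbiased).
#'
#' @param path path to the file.
#' @param axisKind `"wavelength_nm"` (optical) or `"wavenumber_cm-1"` (FTIR).
#' @param signalKind `"fluorescence_emission"`, `"uv_vis_absorbance"` or
#'   `"ftir_absorbance"`.
#' @param label free-text label; defaults to the file name.
#' @return A validated [Spectrum-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("wavelength,intensity", "300,0", "340,1", "380,0"), f)
#' readSpectrum(f)
#' @export
readSpectrum <- function(path, axisKind = "wavelength_nm",
                         signalKind = "fluorescence_emission",
                         label = basename(path)) {
  m <- .readTwoColumn(path)
  if (nrow(m) && anyDuplicated(m[, 1L])) {
    agg <- vapply(split(m[, 2L], m[, 1L]), mean, numeric(1L))
    m <- cbind(as.numeric(names(agg)), unname(agg))
  }
  o <- order(m[, 1L])
  m <- m[o, , drop = FALSE]
  if (nrow(m) < 3L)
    stop(sprintf("need at least 3 distinct points, got %d in %s",
                 nrow(m), path), call. = FALSE)
  Spectrum(m[, 1L], m[, 2L], axisKind = axisKind, signalKind = signalKind,
           label = label)
}

#' Read an absorbance spectrum with Beer-Lambert context
#'
#' As [readSpectrum()] but returns an [AbsorptionSpectrum-class] carrying
#' the absorber concentration and path length needed to convert absorbance
#' to molar absorptivity.
#'
#' @inheritParams readSpectrum
#' @param molarConcentration absorber concentration, mol/L (> 0).
#' @param pathLengthCm optical path length, cm (default 1).
#' @return An [AbsorptionSpectrum-class].
#' @export
readAbsorption <- function(path, molarConcentration, pathLengthCm = 1,
                           label = basename(path)) {
  sp <- readSpectrum(path, axisKind = "wavelength_nm",
                     signalKind = "uv_vis_absorbance", label = label)
  AbsorptionSpectrum(sp@axis, sp@intensity,
                     molarConcentration = molarConcentration,
                     pathLengthCm = pathLengthCm, label = label)
}

#' Read a quenching titration from a two-column text file
#'
#' Reads (concentration, intensity) pairs. The first row must be at zero
#' concentration: its intensity defines the unquenched reference F0.
#' Concentrations must be strictly increasing; out-of-order rows are an
#' error, never silently reordered.
#'
#' @param path path to the file.
#' @param temperatureK temperature of the titration, K.
#' @param peakWavelengthNm monitored emission wavelength (nm), optional.
#' @return A validated [TitrationSeries-class].
#' @export
readTitration <- function(path, temperatureK = 298,
                          peakWavelengthNm = NA_real_) {
  m <- .readTwoColumn(path)
  if (m[1L, 1L] != 0)
    stop("first row must be at zero concentration: F0 (the unquenched ",
         "intensity) is required as the reference", call. = FALSE)
  if (nrow(m) > 1L && any(diff(m[, 1L]) <= 0))
    stop("concentrations must be strictly increasing", call. = FALSE)
  TitrationSeries(m[, 1L], m[, 2L], temperatureK = temperatureK,
                  peakWavelengthNm = peakWavelengthNm)
}

#' Read an excitation-emission matrix from a grid text file
#'
#' The first row holds the emission axis (optionally preceded by a corner
#' label), the first column the excitation axis, and the body the
#' intensities. Returns an [EEMap-class] with an all-`FALSE` mask.
#'
#' @param path path to the file.
#' @return An [EEMap-class].
#' @export
readEEM <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("EEM file needs a header row and at least one data row: %s",
                 path), call. = FALSE)
  head_f <- .splitFields(lines[1L])
  if (is.na(suppressWarnings(as.numeric(head_f[1L]))))
    head_f <- head_f[-1L]  # corner label
  emission <- suppressWarnings(as.numeric(head_f))
  if (anyNA(emission))
    stop("non-numeric value in the emission-axis header row", call. = FALSE)
  nem <- length(emission)
  body <- lines[-1L]
  excitation <- numeric(length(body))
  mat <- matrix(NA_real_, length(body), nem)
  for (i in seq_along(body)) {
    f <- .splitFields(body[i])
    if (length(f) != nem + 1L)
      stop(sprintf("ragged row %d: expected %d cells, got %d",
                   i + 1L, nem + 1L, length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d, column %d: '%s'",
                   i + 1L, j, f[j]), call. = FALSE)
    }
    excitation[i] <- v[1L]
    mat[i, ] <- v[-1L]
  }
  EEMap(excitation, emission, mat)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write a spectrum, titration or EEM back to delimited text
#'
#' Inverses of the corresponding readers; values are written with 17
#' significant digits so the round trip is lossless to at least 12
#' significant digits. `writeEEM` persists intensities only (the scatter
#' mask is a derived quantity; re-apply [maskScatter()] after reading).
#'
#' @param object the object to write.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(object, path) {
  stopifnot(is(object, "Spectrum"))
  writeLines(c("axis,intensity",
               paste(.fmt(object@axis), .fmt(object@intensity), sep = ",")),
             path)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
writeTitration <- function(object, path) {
  stopifnot(is(object, "TitrationSeries"))
  writeLines(c("concentration,intensity",
               paste(.fmt(object@concentrations), .fmt(object@intensities),
                     sep = ",")),
             path)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
writeEEM <- function(object, path) {
  stopifnot(is(object, "EEMap"))
  header <- paste(c("ExEm", .fmt(object@emission)), collapse = ",")
  rows <- vapply(seq_along(object@excitation), function(i)
    paste(c(.fmt(object@excitation[i]), .fmt(object@intensity[i, ])),
          collapse = ","),
    character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
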