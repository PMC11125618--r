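#' @import methods
NULL

.AXIS_KINDS <- c("wavelength_nm", "wavenumber_cm-1")
.SIGNAL_KINDS <- c("fluorescence_emission", "uv_vis_absorbance", "ftir_absorbance")
.STRUCTURE_CLASSES <- c("beta_sheet", "random_coil", "alpha_helix",
                        "beta_turn", "beta_antiparallel")
.FORCE_CLASSES <- c("hydrophobic", "hydrogen_bond_vdW", "electrostatic",
                    "unclassified")

#' Spectrum: a single measured curve
#'
#' One measured spectral curve: a strictly increasing abscissa (wavelength in
#' nm for optical spectra, wavenumber in cm^-1 for FTIR) paired with an
#' intensity or absorbance ordinate. All downstream analyses (quenching,
#' FRET overlap, amide-I deconvolution) consume objects of this class.
#'
#' @slot axis numeric, strictly increasing; nm or cm^-1 depending on
#'   `axisKind`.
#' @slot intensity numeric, same length as `axis`, finite.
#' @slot axisKind one of `"wavelength_nm"`, `"wavenumber_cm-1"`.
#' @slot signalKind one of `"fluorescence_emission"`, `"uv_vis_absorbance"`,
#'   `"ftir_absorbance"`.
#' @slot label free-text description.
#'
#' @seealso [Spectrum()] for the constructor, [readSpectrum()] to read one
#'   from a two-column text file.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(axis = "numeric", intensity = "numeric",
                 axisKind = "character", signalKind = "character",
                 label = "character"),
  prototype(axis = numeric(), intensity = numeric(),
            axisKind = "wavelength_nm", signalKind = "fluorescence_emission",
            label = ""))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@axis) != length(object@intensity))
    msg <- c(msg, "axis and intensity must have equal length")
  if (!all(is.finite(object@axis)))
    msg <- c(msg, "axis values must be finite")
  if (length(object@axis) > 1L && any(diff(object@axis) <= 0))
    msg <- c(msg, "axis must be strictly increasing")
  if (!all(is.finite(object@intensity)))
    msg <- c(msg, "intensity values must be finite")
  if (length(object@axisKind) != 1L || !object@axisKind %in% .AXIS_KINDS)
    msg <- c(msg, sprintf("axisKind must be one of: %s",
                          paste(.AXIS_KINDS, collapse = ", ")))
  if (length(object@signalKind) != 1L || !object@signalKind %in% .SIGNAL_KINDS)
    msg <- c(msg, sprintf("signalKind must be one of: %s",
                          paste(.SIGNAL_KINDS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param axis numeric abscissa (nm or cm^-1), strictly increasing.
#' @param intensity numeric ordinate, same length.
#' @param axisKind `"wavelength_nm"` or `"wavenumber_cm-1"`.
#' @param signalKind `"fluorescence_emission"`, `"uv_vis_absorbance"` or
#'   `"ftir_absorbance"`.
#' @param label free-text label.
#' @return A [Spectrum-class] object.
#' @examples
#' sp <- Spectrum(c(300, 340, 380), c(0, 1, 0))
#' spectrumAxis(sp)
#' @export
Spectrum <- function(axis, intensity, axisKind = "wavelength_nm",
                     signalKind = "fluorescence_emission", label = "") {
  new("Spectrum", axis = as.numeric(axis), intensity = as.numeric(intensity),
      axisKind = axisKind, signalKind = signalKind, label = label)
}

#' AbsorptionSpectrum: absorbance with Beer-Lambert context
#'
#' A [Spectrum-class] measured as UV-Vis absorbance together with the molar
#' concentration of the absorber and the optical path length, so the molar
#' absorptivity epsilon(lambda) = A(lambda) / (c * l) needed by the FRET
#' overlap integral is computable.
#'
#' @slot molarConcentration mol/L, positive.
#' @slot pathLengthCm cm, positive (cuvette path, default 1 cm).
#' @seealso [molarAbsorptivity()], [overlapIntegral()]
#' @exportClass AbsorptionSpectrum
setClass("AbsorptionSpectrum", contains = "Spectrum",
  representation(molarConcentration = "numeric", pathLengthCm = "numeric"),
  prototype(molarConcentration = NA_real_, pathLengthCm = 1,
            signalKind = "uv_vis_absorbance"))

setValidity("AbsorptionSpectrum", function(object) {
  msg <- character()
  if (length(object@molarConcentration) != 1L ||
      !is.finite(object@molarConcentration) || object@molarConcentration <= 0)
    msg <- c(msg, "molarConcentration must be a single positive value (mol/L)")
  if (length(object@pathLengthCm) != 1L ||
      !is.finite(object@pathLengthCm) || object@pathLengthCm <= 0)
    msg <- c(msg, "pathLengthCm must be a single positive value (cm)")
  if (length(msg)) msg else TRUE
})

#' Construct an AbsorptionSpectrum
#'
#' @inheritParams Spectrum
#' @param absorbance numeric absorbance values (dimensionless).
#' @param molarConcentration absorber concentration, mol/L (> 0).
#' @param pathLengthCm optical path length, cm (> 0).
#' @return An [AbsorptionSpectrum-class].
#' @examples
#' ab <- AbsorptionSpectrum(330:360, rep(0.1, 31), molarConcentration = 1e-5)
#' range(molarAbsorptivity(ab))
#' @export
AbsorptionSpectrum <- function(axis, absorbance, molarConcentration,
                               pathLengthCm = 1, label = "") {
  new("AbsorptionSpectrum", axis = as.numeric(axis),
      intensity = as.numeric(absorbance), axisKind = "wavelength_nm",
      signalKind = "uv_vis_absorbance", label = label,
      molarConcentration = molarConcentration, pathLengthCm = pathLengthCm)
}

#' TitrationSeries: a fluorescence quenching titration
#'
#' Ligand (quencher) concentrations with matched fluorescence intensities
#' read at the monitored emission peak at one temperature. The first
#' concentration must be zero; its intensity is the unquenched reference F0.
#'
#' @slot concentrations mol/L, strictly increasing from 0.
#' @slot intensities fluorescence at the emission peak, positive, same length.
#' @slot temperatureK Kelvin.
#' @slot peakWavelengthNm emission wavelength monitored (nm); may be `NA`.
#' @seealso [TitrationSeries()], [fitSternVolmer()], [fitDoubleLog()]
#' @exportClass TitrationSeries
setClass("TitrationSeries",
  representation(concentrations = "numeric", intensities = "numeric",
                 temperatureK = "numeric", peakWavelengthNm = "numeric"),
  prototype(temperatureK = 298, peakWavelengthNm = NA_real_))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (length(object@concentrations) != length(object@intensities))
    msg <- c(msg, "concentrations and intensities must have equal length")
  if (length(object@concentrations) &&
      (!is.finite(object@concentrations[1L]) || object@concentrations[1L] != 0))
    msg <- c(msg, "first concentration must be 0 (defines F0)")
  if (length(object@concentrations) > 1L &&
      any(diff(object@concentrations) <= 0))
    msg <- c(msg, "concentrations must be strictly increasing")
  if (!all(is.finite(object@intensities) & object@intensities > 0))
    msg <- c(msg, "intensities must be finite and positive")
  if (length(object@temperatureK) != 1L ||
      !is.finite(object@temperatureK) || object@temperatureK <= 0)
    msg <- c(msg, "temperatureK must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Construct a TitrationSeries
#'
#' @param concentrations quencher concentrations, mol/L, strictly increasing
#'   with the first equal to 0.
#' @param intensities fluorescence intensities, positive, same length.
#' @param temperatureK temperature in Kelvin.
#' @param peakWavelengthNm monitored emission wavelength (nm), optional.
#' @return A [TitrationSeries-class].
#' @examples
#' ts <- TitrationSeries(c(0, 1e-7, 2e-7), c(100, 83, 71), temperatureK = 298)
#' F0(ts)
#' @export
TitrationSeries <- function(concentrations, intensities, temperatureK = 298,
                            peakWavelengthNm = NA_real_) {
  new("TitrationSeries", concentrations = as.numeric(concentrations),
      intensities = as.numeric(intensities),
      temperatureK = as.numeric(temperatureK),
      peakWavelengthNm = as.numeric(peakWavelengthNm))
}

#' EEMap: an excitation-emission matrix
#'
#' Fluorescence intensity over a 2-D grid of excitation and emission
#' wavelengths, with a logical mask marking cells excluded from peak
#' statistics (scatter ridges). Rows index excitation, columns emission.
#'
#' @slot excitation excitation axis, nm, strictly increasing.
#' @slot emission emission axis, nm, strictly increasing.
#' @slot intensity matrix, `length(excitation)` x `length(emission)`.
#' @slot mask logical matrix, same shape; `TRUE` = excluded.
#' @seealso [maskScatter()], [eemPeaks()], [compareEEMs()]
#' @exportClass EEMap
setClass("EEMap",
  representation(excitation = "numeric", emission = "numeric",
                 intensity = "matrix", mask = "matrix"))

setValidity("EEMap", function(object) {
  msg <- character()
  if (length(object@excitation) > 1L && any(diff(object@excitation) <= 0))
    msg <- c(msg, "excitation axis must be strictly increasing")
  if (length(object@emission) > 1L && any(diff(object@emission) <= 0))
    msg <- c(msg, "emission axis must be strictly increasing")
  if (!identical(dim(object@intensity),
                 c(length(object@excitation), length(object@emission))))
    msg <- c(msg, "intensity matrix must be excitation x emission")
  if (!is.logical(object@mask) ||
      !identical(dim(object@mask), dim(object@intensity)))
    msg <- c(msg, "mask must be a logical matrix of the same shape")
  if (!all(is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EEMap
#'
#' @param excitation excitation wavelengths (nm), strictly increasing.
#' @param emission emission wavelengths (nm), strictly increasing.
#' @param intensity numeric matrix, rows = excitation, columns = emission.
#' @param mask optional logical matrix of scatter-excluded cells; defaults to
#'   all-`FALSE`.
#' @return An [EEMap-class].
#' @export
EEMap <- function(excitation, emission, intensity, mask = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(mask))
    mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  new("EEMap", excitation = as.numeric(excitation),
      emission = as.numeric(emission), intensity = intensity,
      mask = mask)
}

#' QuenchingResult: Stern-Volmer and double-log fit outputs
#'
#' Holds the Stern-Volmer quenching constant Ksv (L/mol), the bimolecular
#' quenching rate constant Kq = Ksv / tau0 (L/mol/s), the apparent binding
#' constant Ka (L/mol) and binding-site number n from the double-logarithm
#' model, fit diagnostics, and the static/dynamic mechanism verdict. Fields
#' not populated by a given fit are `NA`.
#'
#' @slot Ksv Stern-Volmer constant, L/mol.
#' @slot Kq bimolecular quenching rate constant, L/mol/s; always `Ksv/tau0`.
#' @slot tau0 unquenched fluorophore lifetime, s.
#' @slot Ka apparent binding constant, L/mol.
#' @slot n binding-site number (dimensionless).
#' @slot interceptSV free intercept of the Stern-Volmer line.
#' @slot rSquaredSV,rSquaredDL coefficients of determination of the two fits.
#' @slot mechanism `"static"`, `"dynamic"`, or `NA`.
#' @slot temperatureK temperature of the underlying titration, K.
#' @slot notes character vector of diagnostic flags (e.g. intercept drift,
#'   points dropped from the double-log fit).
#' @exportClass QuenchingResult
setClass("QuenchingResult",
  representation(Ksv = "numeric", Kq = "numeric", tau0 = "numeric",
                 Ka = "numeric", n = "numeric", interceptSV = "numeric",
                 rSquaredSV = "numeric", rSquaredDL = "numeric",
                 mechanism = "character", temperatureK = "numeric",
                 notes = "character"),
  prototype(Ksv = NA_real_, Kq = NA_real_, tau0 = 1e-8, Ka = NA_real_,
            n = NA_real_, interceptSV = NA_real_, rSquaredSV = NA_real_,
            rSquaredDL = NA_real_, mechanism = NA_character_,
            temperatureK = NA_real_, notes = character()))

setValidity("QuenchingResult", function(object) {
  msg <- character()
  if (is.finite(object@Ksv) && is.finite(object@Kq) &&
      object@Kq != object@Ksv / object@tau0)
    msg <- c(msg, "Kq must equal Ksv / tau0 exactly")
  if (is.finite(object@Ka) && object@Ka <= 0)
    msg <- c(msg, "Ka must be positive")
  if (!is.na(object@mechanism) &&
      !object@mechanism %in% c("static", "dynamic"))
    msg <- c(msg, "mechanism must be 'static' or 'dynamic'")
  if (length(msg)) msg else TRUE
})

#' FretResult: Forster energy-transfer outputs
#'
#' Overlap integral J (cm^3 L / mol), Forster radius R0 (nm), transfer
#' efficiency E, donor-acceptor distance r (nm), the constants used
#' (orientation factor K^2, refractive index N, donor quantum yield Phi),
#' and the energy-transfer validity verdict (r within 0.5-1.5 R0 and below
#' 7 nm).
#'
#' @slot J overlap integral, cm^3 L / mol.
#' @slot R0 Forster radius, nm.
#' @slot E transfer efficiency in `[0, 1]`.
#' @slot r donor-acceptor distance, nm.
#' @slot K2 orientation factor (default 2/3).
#' @slot N medium refractive index (default 1.34).
#' @slot phi donor fluorescence quantum yield (default 0.15).
#' @slot valid logical energy-transfer validity verdict.
#' @slot reasons character vector of failed validity conditions.
#' @exportClass FretResult
setClass("FretResult",
  representation(J = "numeric", R0 = "numeric", E = "numeric", r = "numeric",
                 K2 = "numeric", N = "numeric", phi = "numeric",
                 valid = "logical", reasons = "character"),
  prototype(J = NA_real_, R0 = NA_real_, E = NA_real_, r = NA_real_,
            K2 = 2 / 3, N = 1.34, phi = 0.15, valid = NA,
            reasons = character()))

setValidity("FretResult", function(object) {
  msg <- character()
  if (is.finite(object@J) && object@J < 0) msg <- c(msg, "J must be >= 0")
  if (is.finite(object@R0) && object@R0 < 0) msg <- c(msg, "R0 must be >= 0")
  if (is.finite(object@E) && (object@E < 0 || object@E > 1))
    msg <- c(msg, "E must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ThermoResult: van't Hoff thermodynamics of binding
#'
#' Binding enthalpy, entropy, Gibbs free energy per temperature, and the
#' binding-force classification from the sign pattern of (dH, dS).
#'
#' @slot deltaH kJ/mol.
#' @slot deltaS J/mol/K.
#' @slot deltaG named numeric, kJ/mol keyed by temperature (K); each value
#'   satisfies dG = dH - T dS.
#' @slot forceClass `"hydrophobic"`, `"hydrogen_bond_vdW"`,
#'   `"electrostatic"` or `"unclassified"`.
#' @slot Rgas gas constant used, J/mol/K (8.314).
#' @exportClass ThermoResult
setClass("ThermoResult",
  representation(deltaH = "numeric", deltaS = "numeric", deltaG = "numeric",
                 forceClass = "character", Rgas = "numeric"),
  prototype(deltaH = NA_real_, deltaS = NA_real_, deltaG = numeric(),
            forceClass = NA_character_, Rgas = 8.314))

setValidity("ThermoResult", function(object) {
  msg <- character()
  if (length(object@deltaG)) {
    Tk <- suppressWarnings(as.numeric(names(object@deltaG)))
    if (any(is.na(Tk)))
      msg <- c(msg, "deltaG must be named by temperature (K)")
    else if (is.finite(object@deltaH) && is.finite(object@deltaS)) {
      expect <- object@deltaH - Tk * object@deltaS / 1000
      if (any(abs(expect - object@deltaG) > 1e-9))
        msg <- c(msg, "deltaG entries must satisfy dG = dH - T dS")
    }
  }
  if (!is.na(object@forceClass) && !object@forceClass %in% .FORCE_CLASSES)
    msg <- c(msg, sprintf("forceClass must be one of: %s",
                          paste(.FORCE_CLASSES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SecondaryStructure: amide-I composition summary
#'
#' Area percentages per secondary-structure class obtained from amide-I band
#' deconvolution, together with the fitted band table.
#'
#' @slot percent named numeric over the five structure classes
#'   (`beta_sheet`, `random_coil`, `alpha_helix`, `beta_turn`,
#'   `beta_antiparallel`); sums to 100.
#' @slot bands data.frame of fitted bands (center, sigma, amplitude, area,
#'   assignment).
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
  representation(percent = "numeric", bands = "data.frame"),
  prototype(percent = stats::setNames(rep(NA_real_, 5), .STRUCTURE_CLASSES),
            bands = data.frame()))

setValidity("SecondaryStructure", function(object) {
  msg <- character()
  if (!identical(names(object@percent), .STRUCTURE_CLASSES))
    msg <- c(msg, sprintf("percent must be named: %s",
                          paste(.STRUCTURE_CLASSES, collapse = ", ")))
  else if (all(is.finite(object@percent))) {
    if (any(object@percent < 0)) msg <- c(msg, "percentages must be >= 0")
    if (abs(sum(object@percent) - 100) > 0.1)
      msg <- c(msg, "percentages must sum to 100 within 0.1")
  }
  if (length(msg)) msg else TRUE
})

#' StudyReport: collated outputs of a full binding study
#'
#' Per-ligand result blocks (quenching, FRET, thermodynamics, ligand
#' efficiency, FTIR secondary structure, EEM shifts) plus a provenance block
#' recording the configuration, seed, package version and input-file digests.
#'
#' @slot ligands named list; one list of result blocks per ligand.
#' @slot provenance list: config used, seed, version, file digests.
#' @seealso [runFullStudy()], [writeStudyReport()]
#' @exportClass StudyReport
setClass("StudyReport",
  representation(ligands = "list", provenance = "list"),
  prototype(ligands = list(), provenance = list()))
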