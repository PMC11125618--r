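# Accessor generics and show methods for the data classes.

#' @describeIn Spectrum-class abscissa values (nm or cm^-1)
#' @param object,x a package object
#' @export
setGeneric("spectrumAxis", function(object) standardGeneric("spectrumAxis"))
#' @rdname Spectrum-class
#' @export
setMethod("spectrumAxis", "Spectrum", function(object) object@axis)

#' @describeIn Spectrum-class ordinate values
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname Spectrum-class
#' @export
setMethod("intensity", "Spectrum", function(object) object@intensity)
#' @rdname EEMap-class
#' @export
setMethod("intensity", "EEMap", function(object) object@intensity)

#' @describeIn Spectrum-class axis kind string
#' @export
setGeneric("axisKind", function(object) standardGeneric("axisKind"))
#' @rdname Spectrum-class
#' @export
setMethod("axisKind", "Spectrum", function(object) object@axisKind)

#' @describeIn Spectrum-class signal kind string
#' @export
setGeneric("signalKind", function(object) standardGeneric("signalKind"))
#' @rdname Spectrum-class
#' @export
setMethod("signalKind", "Spectrum", function(object) object@signalKind)

#' @describeIn Spectrum-class number of points
#' @export
setMethod("length", "Spectrum", function(x) length(x@axis))

#' @describeIn AbsorptionSpectrum-class molar absorptivity
#'   epsilon(lambda) = A(lambda) / (c l), in L/mol/cm
#' @param object an `AbsorptionSpectrum`
#' @export
setGeneric("molarAbsorptivity",
           function(object) standardGeneric("molarAbsorptivity"))
#' @rdname AbsorptionSpectrum-class
#' @export
setMethod("molarAbsorptivity", "AbsorptionSpectrum", function(object)
  object@intensity / (object@molarConcentration * object@pathLengthCm))

#' @describeIn TitrationSeries-class quencher concentrations (mol/L)
#' @param object a `TitrationSeries`
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))
#' @rdname TitrationSeries-class
#' @export
setMethod("concentrations", "TitrationSeries",
          function(object) object@concentrations)

#' @describeIn TitrationSeries-class fluorescence intensities
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname TitrationSeries-class
#' @export
setMethod("intensities", "TitrationSeries", function(object) object@intensities)

#' @describeIn TitrationSeries-class temperature (K)
#' @export
setGeneric("temperatureK", function(object) standardGeneric("temperatureK"))
#' @rdname TitrationSeries-class
#' @export
setMethod("temperatureK", "TitrationSeries", function(object) object@temperatureK)

#' @describeIn TitrationSeries-class unquenched reference intensity
#'   (at zero quencher)
#' @export
setGeneric("F0", function(object) standardGeneric("F0"))
#' @rdname TitrationSeries-class
#' @export
setMethod("F0", "TitrationSeries", function(object) object@intensities[1L])

#' @describeIn EEMap-class excitation axis (nm)
#' @param object an `EEMap`
#' @export
setGeneric("excitationAxis", function(object) standardGeneric("excitationAxis"))
#' @rdname EEMap-class
#' @export
setMethod("excitationAxis", "EEMap", function(object) object@excitation)

#' @describeIn EEMap-class emission axis (nm)
#' @export
setGeneric("emissionAxis", function(object) standardGeneric("emissionAxis"))
#' @rdname EEMap-class
#' @export
setMethod("emissionAxis", "EEMap", function(object) object@emission)

#' @describeIn EEMap-class logical mask of scatter-excluded cells
#' @export
setGeneric("eemMask", function(object) standardGeneric("eemMask"))
#' @rdname EEMap-class
#' @export
setMethod("eemMask", "EEMap", function(object) object@mask)

#' @describeIn SecondaryStructure-class area percentages per class
#' @param object a `SecondaryStructure`
#' @export
setGeneric("structurePercent",
           function(object) standardGeneric("structurePercent"))
#' @rdname SecondaryStructure-class
#' @export
setMethod("structurePercent", "SecondaryStructure",
          function(object) object@percent)

#' @describeIn SecondaryStructure-class fitted amide-I band table
#' @export
setGeneric("amideBands", function(object) standardGeneric("amideBands"))
#' @rdname SecondaryStructure-class
#' @export
setMethod("amideBands", "SecondaryStructure", function(object) object@bands)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("%s of %d points, %s [%g, %g], %s\n",
              class(object), length(object@axis), object@axisKind,
              if (length(object@axis)) min(object@axis) else NA,
              if (length(object@axis)) max(object@axis) else NA,
              object@signalKind))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d points, T = %g K, F0 = %g\n",
              length(object@concentrations), object@temperatureK,
              object@intensities[1L]))
  cat(sprintf("  [Q] from %g to %g mol/L\n",
              min(object@concentrations), max(object@concentrations)))
})

setMethod("show", "EEMap", function(object) {
  cat(sprintf("EEMap: %d x %d (excitation x emission), %d cell(s) masked\n",
              length(object@excitation), length(object@emission),
              sum(object@mask)))
})

setMethod("show", "QuenchingResult", function(object) {
  cat("Quenching analysis\n")
  cat(sprintf("  Ksv = %.4g L/mol (intercept %.4g, R^2 = %.4f)\n",
              object@Ksv, object@interceptSV, object@rSquaredSV))
  cat(sprintf("  Kq  = %.4g L/mol/s (tau0 = %g s) -> %s quenching\n",
              object@Kq, object@tau0, object@mechanism))
  cat(sprintf("  Ka  = %.4g L/mol, n = %.3f (R^2 = %.4f)\n",
              object@Ka, object@n, object@rSquaredDL))
  for (w in object@notes) cat("  note:", w, "\n")
})

setMethod("show", "FretResult", function(object) {
  cat("Forster energy transfer\n")
  cat(sprintf("  J  = %.4g cm^3 L / mol\n", object@J))
  cat(sprintf("  R0 = %.3f nm (K^2 = %.4g, N = %.3g, Phi = %.3g)\n",
              object@R0, object@K2, object@N, object@phi))
  cat(sprintf("  E  = %.3f, r = %.3f nm\n", object@E, object@r))
  if (isTRUE(object@valid)) {
    cat("  energy-transfer conditions satisfied\n")
  } else if (identical(object@valid, FALSE)) {
    cat("  conditions violated:", paste(object@reasons, collapse = "; "), "\n")
  }
})

setMethod("show", "ThermoResult", function(object) {
  cat("Thermodynamics of binding\n")
  cat(sprintf("  dH = %.4g kJ/mol, dS = %.4g J/mol/K -> %s\n",
              object@deltaH, object@deltaS, object@forceClass))
  for (i in seq_along(object@deltaG))
    cat(sprintf("  dG(%s K) = %.4g kJ/mol\n",
                names(object@deltaG)[i], object@deltaG[i]))
})

setMethod("show", "SecondaryStructure", function(object) {
  cat("Secondary structure (amide-I deconvolution)\n")
  for (cl in names(object@percent))
    cat(sprintf("  %-17s %6.2f %%\n", cl, object@percent[cl]))
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d ligand block(s): %s\n",
              length(object@ligands),
              paste(names(object@ligands), collapse = ", ")))
})
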