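# Van't Hoff thermodynamics of binding, binding-force classification from
# the sign pattern of (dH, dS), and docking-derived ligand efficiency.
#
#   ln(K2/K1) = dH (1/T1 - 1/T2) / R
#   dG = -R T ln Ka
#   dG = dH - T dS
#   LE = |dG_binding| / N_heavy

.RGAS <- 8.314  # J / mol / K

#' Binding enthalpy from the temperature dependence of Ka
#'
#' For exactly two temperatures this is the two-point van't Hoff relation
#' dH = R ln(K2/K1) / (1/T1 - 1/T2); for more, the slope of an ordinary
#' least-squares fit of ln Ka on 1/T gives dH = -slope * R, which reduces to
#' the two-point formula when only two points are supplied.
#'
#' @param Ka apparent binding constants, L/mol, all positive.
#' @param temperatures matching temperatures, K, all distinct.
#' @return dH in kJ/mol.
#' @examples
#' vantHoffEnthalpy(c(1e6, 2e6), c(293, 303))  # 51.16 kJ/mol
#' @export
vantHoffEnthalpy <- function(Ka, temperatures) {
  if (length(Ka) != length(temperatures) || length(Ka) < 2L)
    stop("'Ka' and 'temperatures' must be matched vectors of length >= 2",
         call. = FALSE)
  if (any(!is.finite(Ka)) || any(Ka <= 0))
    stop("all Ka must be positive", call. = FALSE)
  if (anyDuplicated(temperatures))
    stop("temperatures must be distinct", call. = FALSE)
  if (any(temperatures <= 0))
    stop("temperatures must be positive (Kelvin)", call. = FALSE)
  fit <- .ols(1 / temperatures, log(Ka))
  -fit$slope * .RGAS / 1000
}

#' Gibbs free energy from the binding constant
#'
#' dG = -R T ln Ka, in kJ/mol.
#'
#' @param Ka apparent binding constant, L/mol (> 0).
#' @param temperatureK temperature, K (> 0).
#' @return dG in kJ/mol.
#' @examples
#' gibbsFromKa(1e6, 298)  # -34.23 kJ/mol
#' @export
gibbsFromKa <- function(Ka, temperatureK) {
  .assertScalarNumber(Ka, "Ka")
  .assertScalarNumber(temperatureK, "temperatureK")
  if (Ka <= 0) stop("'Ka' must be positive", call. = FALSE)
  if (temperatureK <= 0)
    stop("'temperatureK' must be positive", call. = FALSE)
  -.RGAS * temperatureK * log(Ka) / 1000
}

#' Gibbs free energy from enthalpy and entropy
#'
#' dG = dH - T dS, with dH in kJ/mol and dS in J/mol/K (the conventional
#' reporting units; the factor 1000 is handled internally).
#'
#' @param deltaH kJ/mol.
#' @param deltaS J/mol/K.
#' @param temperatureK K (> 0).
#' @return dG in kJ/mol.
#' @examples
#' gibbsFromHS(21.95, 190.11, 293)  # -33.75 kJ/mol
#' @export
gibbsFromHS <- function(deltaH, deltaS, temperatureK) {
  .assertScalarNumber(deltaH, "deltaH")
  .assertScalarNumber(deltaS, "deltaS")
  .assertScalarNumber(temperatureK, "temperatureK")
  if (temperatureK <= 0)
    stop("'temperatureK' must be positive", call. = FALSE)
  deltaH - temperatureK * deltaS / 1000
}

#' Classify the dominant binding force from the signs of dH and dS
#'
#' Positive dH and dS indicate hydrophobic forces; both negative indicate
#' hydrogen bonding and van der Waals interactions; dH < 0 with dS > 0
#' indicates electrostatic attraction. The remaining sign pattern (dH > 0,
#' dS < 0) and near-zero values (within 1e-9) are reported as
#' `"unclassified"`, the latter with a warning.
#'
#' @param deltaH kJ/mol.
#' @param deltaS J/mol/K.
#' @return One of `"hydrophobic"`, `"hydrogen_bond_vdW"`,
#'   `"electrostatic"`, `"unclassified"`.
#' @examples
#' classifyForces(21.95, 190.11)  # hydrophobic
#' @export
classifyForces <- function(deltaH, deltaS) {
  .assertScalarNumber(deltaH, "deltaH")
  .assertScalarNumber(deltaS, "deltaS")
  eps <- 1e-9
  if (abs(deltaH) <= eps || abs(deltaS) <= eps) {
    warning("dH or dS indistinguishable from zero; force unclassified",
            call. = FALSE)
    return("unclassified")
  }
  if (deltaH > 0 && deltaS > 0) return("hydrophobic")
  if (deltaH < 0 && deltaS < 0) return("hydrogen_bond_vdW")
  if (deltaH < 0 && deltaS > 0) return("electrostatic")
  "unclassified"
}

#' Full van't Hoff analysis over a set of temperatures
#'
#' Fits ln Ka against 1/T: the slope gives dH = -slope R, the intercept
#' gives dS = R * intercept, and dG at each input temperature is computed
#' as dH - T dS so the stored values satisfy the Gibbs identity exactly.
#'
#' @inheritParams vantHoffEnthalpy
#' @return A [ThermoResult-class].
#' @examples
#' vantHoffAnalysis(c(1.0e6, 1.5e6, 2.2e6), c(293, 298, 303))
#' @export
vantHoffAnalysis <- function(Ka, temperatures) {
  dH <- vantHoffEnthalpy(Ka, temperatures)
  fit <- .ols(1 / temperatures, log(Ka))
  dS <- .RGAS * fit$intercept
  dG <- dH - temperatures * dS / 1000
  names(dG) <- format(temperatures, trim = TRUE)
  new("ThermoResult", deltaH = dH, deltaS = dS, deltaG = dG,
      forceClass = classifyForces(dH, dS), Rgas = .RGAS)
}

#' Count non-hydrogen atoms in a molecular formula
#'
#' Parses a Hill-style molecular formula (e.g. `"C4F9O3S"`) and sums the
#' atom counts of every element except hydrogen. For salts, supply the
#' anion formula: counter-ions (e.g. a trailing K of a potassium salt)
#' would otherwise inflate the count.
#'
#' @param formula molecular formula string.
#' @return Integer heavy-atom count.
#' @examples
#' heavyAtomCount("C4F9O3S")  # 17
#' heavyAtomCount("H2O")      # 1
#' @export
heavyAtomCount <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("'formula' must be a single non-empty string", call. = FALSE)
  rest <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", rest)[[1L]]
  tokens <- regmatches(rest, gregexpr("([A-Z][a-z]?)([0-9]*)", rest))[[1L]]
  if (!length(tokens) || sum(attr(m, "match.length")) != nchar(rest))
    stop(sprintf("cannot parse molecular formula: '%s'", formula),
         call. = FALSE)
  total <- 0L
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% .PERIODIC_SYMBOLS)
      stop(sprintf("unknown element symbol '%s' in formula '%s'",
                   el, formula), call. = FALSE)
    if (el != "H") total <- total + cnt
  }
  total
}

#' Ligand efficiency from a docking binding energy
#'
#' LE = |binding energy| / N_heavy, in kcal/mol per heavy atom, reported as
#' a positive magnitude (binding energies are negative when favourable).
#'
#' @param bindingEnergyKcal docking binding energy, kcal/mol.
#' @param nHeavy number of non-hydrogen atoms (>= 1), e.g. from
#'   [heavyAtomCount()].
#' @return LE, kcal/mol per heavy atom.
#' @examples
#' ligandEfficiency(-5.196, heavyAtomCount("C4F9O3S"))  # 0.306
#' @export
ligandEfficiency <- function(bindingEnergyKcal, nHeavy) {
  .assertScalarNumber(bindingEnergyKcal, "bindingEnergyKcal")
  if (!is.numeric(nHeavy) || length(nHeavy) != 1L || nHeavy < 1 ||
      nHeavy != round(nHeavy))
    stop("'nHeavy' must be a positive integer", call. = FALSE)
  abs(bindingEnergyKcal) / nHeavy
}

#' Ligand record: formula, binding energy, heavy atoms, efficiency
#'
#' Convenience constructor bundling [heavyAtomCount()] and
#' [ligandEfficiency()] into a one-row data.frame.
#'
#' @param name ligand name.
#' @param formula molecular formula (anion formula for salts).
#' @param bindingEnergyKcal docking binding energy, kcal/mol.
#' @return A one-row data.frame with columns `name`, `formula`,
#'   `binding_energy_kcal`, `n_heavy`, `LE`.
#' @examples
#' ligandRecord("PFBS", "C4F9O3S", -5.196)
#' @export
ligandRecord <- function(name, formula, bindingEnergyKcal) {
  nh <- heavyAtomCount(formula)
  data.frame(name = name, formula = formula,
             binding_energy_kcal = bindingEnergyKcal, n_heavy = nh,
             LE = ligandEfficiency(bindingEnergyKcal, nh),
             stringsAsFactors = FALSE)
}
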