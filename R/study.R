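# Full-study runner: executes every stage for which the configuration
# names inputs (quenching -> FRET -> thermodynamics -> ligand efficiency ->
# FTIR -> EEM) and collates the derived constants into a StudyReport.

.asListQuenching <- function(x) list(
  Ksv = x@Ksv, Kq = x@Kq, tau0 = x@tau0, Ka = x@Ka, n = x@n,
  intercept_sv = x@interceptSV, r_squared_sv = x@rSquaredSV,
  r_squared_dl = x@rSquaredDL, mechanism = x@mechanism,
  temperature_K = x@temperatureK, notes = x@notes)

.asListFret <- function(x) list(
  J = x@J, R0_nm = x@R0, E = x@E, r_nm = x@r, K2 = x@K2, N = x@N,
  phi = x@phi, valid = x@valid, reasons = x@reasons)

.asListThermo <- function(x) list(
  delta_H_kJ = x@deltaH, delta_S_J = x@deltaS,
  delta_G_kJ_by_T = as.list(x@deltaG), force_class = x@forceClass,
  R_gas = x@Rgas)

.asListStructure <- function(x) list(
  percent = as.list(x@percent),
  bands = x@bands)

#' Run a full binding study from a configuration
#'
#' Executes, for each configured ligand, every stage whose inputs are
#' present: per-temperature quenching fits, van't Hoff thermodynamics
#' (when at least two temperatures are available), FRET analysis, ligand
#' efficiency, FTIR secondary structure, and EEM shift analysis. Absent
#' inputs skip their stage with a logged notice; a failing stage is
#' recorded in the report as an error annotation and raised as a warning,
#' so a partial report is always produced.
#'
#' @param config either a path to a YAML configuration file or an
#'   equivalent named list. Top level: optional `seed`, optional
#'   `constants` (`tau0`, `K2`, `N`, `phi`, `scatter_half_width`), and
#'   `ligands`, a named list. Per ligand: `titrations` (list of
#'   `file`/`temperature` pairs), `emission_file`, `absorption_file`,
#'   `absorption_concentration`, `path_length_cm`, `fret_F`, `fret_F0`,
#'   `formula`, `binding_energy_kcal`, `ftir_file`, `eem_reference_file`,
#'   `eem_treated_file`. Every entry is optional.
#' @param quiet suppress per-stage notices.
#' @return A [StudyReport-class].
#' @seealso [writeStudyReport()], [readStudyReport()]
#' @export
runFullStudy <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a file path",
                             call. = FALSE)
  say <- function(...) if (!quiet) message(...)
  const <- config$constants
  tau0 <- const$tau0 %||% 1e-8
  K2 <- const$K2 %||% (2 / 3)
  Nref <- const$N %||% 1.34
  phi <- const$phi %||% 0.15
  scatterHW <- const$scatter_half_width %||% 15
  files <- character()
  note_file <- function(f) files <<- unique(c(files, f))
  run_stage <- function(block, name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("stage '%s' failed: %s", name, conditionMessage(res)),
              call. = FALSE)
      block$errors[[name]] <- conditionMessage(res)
    } else if (!is.null(res)) {
      block[[name]] <- res
    }
    block
  }
  ligands <- list()
  for (lig in names(config$ligands)) {
    cfg <- config$ligands[[lig]]
    block <- list(errors = list())
    # quenching and van't Hoff thermodynamics
    if (!is.null(cfg$titrations)) {
      block <- run_stage(block, "quenching", {
        qres <- lapply(cfg$titrations, function(tt) {
          note_file(tt$file)
          series <- readTitration(tt$file,
                                  temperatureK = tt$temperature %||% 298)
          .asListQuenching(quenchingAnalysis(series, tau0 = tau0))
        })
        names(qres) <- vapply(qres, function(z)
          format(z$temperature_K, trim = TRUE), character(1L))
        qres
      })
      if (!is.null(block$quenching) && length(block$quenching) >= 2L) {
        block <- run_stage(block, "thermo", {
          Ka <- vapply(block$quenching, `[[`, numeric(1L), "Ka")
          Tk <- vapply(block$quenching, `[[`, numeric(1L), "temperature_K")
          .asListThermo(vantHoffAnalysis(Ka, Tk))
        })
      }
    } else say("[", lig, "] no titrations: quenching stage skipped")
    # FRET
    if (!is.null(cfg$emission_file) && !is.null(cfg$absorption_file) &&
        !is.null(cfg$fret_F) && !is.null(cfg$fret_F0)) {
      block <- run_stage(block, "fret", {
        note_file(cfg$emission_file); note_file(cfg$absorption_file)
        em <- readSpectrum(cfg$emission_file)
        ab <- readAbsorption(cfg$absorption_file,
                             molarConcentration =
                               cfg$absorption_concentration %||% 1e-5,
                             pathLengthCm = cfg$path_length_cm %||% 1)
        .asListFret(fretAnalysis(em, ab, F = cfg$fret_F, F0 = cfg$fret_F0,
                                 K2 = K2, N = Nref, phi = phi))
      })
    } else say("[", lig, "] FRET inputs incomplete: stage skipped")
    # ligand efficiency
    if (!is.null(cfg$formula) && !is.null(cfg$binding_energy_kcal)) {
      block <- run_stage(block, "ligand_efficiency",
        as.list(ligandRecord(lig, cfg$formula, cfg$binding_energy_kcal)))
    } else say("[", lig, "] no docking inputs: ligand-efficiency stage skipped")
    # FTIR
    if (!is.null(cfg$ftir_file)) {
      block <- run_stage(block, "secondary_structure", {
        note_file(cfg$ftir_file)
        sp <- readSpectrum(cfg$ftir_file, axisKind = "wavenumber_cm-1",
                           signalKind = "ftir_absorbance")
        .asListStructure(ftirSecondaryStructure(sp))
      })
    } else say("[", lig, "] no FTIR spectrum: stage skipped")
    # EEM
    if (!is.null(cfg$eem_reference_file) && !is.null(cfg$eem_treated_file)) {
      block <- run_stage(block, "eem_shifts", {
        note_file(cfg$eem_reference_file); note_file(cfg$eem_treated_file)
        ref <- maskScatter(readEEM(cfg$eem_reference_file), scatterHW)
        trt <- maskScatter(readEEM(cfg$eem_treated_file), scatterHW)
        compareEEMs(ref, trt)
      })
    } else say("[", lig, "] EEM pair incomplete: stage skipped")
    if (!length(block$errors)) block$errors <- NULL
    ligands[[lig]] <- block
  }
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  new("StudyReport", ligands = ligands,
      provenance = list(
        config = config,
        seed = config$seed %||% NA_integer_,
        version = as.character(utils::packageVersion("specbind")),
        file_md5 = digests))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study report to JSON or plain text
#'
#' The JSON form serialises every number at full precision and contains no
#' timestamps, so identical inputs and configuration give byte-identical
#' reports; [readStudyReport()] re-parses it losslessly.
#'
#' @param report a [StudyReport-class].
#' @param path destination file.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
writeStudyReport <- function(report, path, format = c("json", "text")) {
  stopifnot(is(report, "StudyReport"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(ligands = report@ligands,
                              provenance = report@provenance),
                         path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (lig in names(report@ligands)) {
      writeLines(sprintf("== %s ==", lig), con)
      blk <- report@ligands[[lig]]
      for (stage in names(blk)) {
        writeLines(sprintf("-- %s --", stage), con)
        writeLines(utils::capture.output(utils::str(blk[[stage]],
                                                    digits.d = 6)), con)
      }
    }
  }
  invisible(path)
}

#' @rdname writeStudyReport
#' @return `readStudyReport` returns the parsed report as a list with
#'   elements `ligands` and `provenance`.
#' @export
readStudyReport <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
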