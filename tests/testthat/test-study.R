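make_study_dir <- function() {
  dir <- tempfile("study")
  dir.create(dir)
  # titrations at three temperatures; mild Ka increase with T
  Kas <- c(`293` = 1.6e6, `298` = 1.9e6, `303` = 2.2e6)
  for (Tk in names(Kas)) {
    ts <- genTitration(Ka = Kas[[Tk]], n = 1, noiseFraction = 0,
                       temperatureK = as.numeric(Tk))
    writeTitration(ts, file.path(dir, paste0("titration_", Tk, ".csv")))
  }
  sp <- genOpticalSpectra(noiseFraction = 0)
  writeSpectrum(sp$emission, file.path(dir, "emission.csv"))
  writeSpectrum(sp$absorption, file.path(dir, "absorption.csv"))
  writeSpectrum(genAmideComposite(fractions = c(0.2, 0.15, 0.3, 0.2, 0.15),
                                  noiseFraction = 0.005, seed = 2),
                file.path(dir, "ftir.csv"))
  writeEEM(genEEM(noiseFraction = 0), file.path(dir, "eem_ref.csv"))
  shifted <- genEEM(peaks = data.frame(
    excitation = c(280, 230), emission = c(335, 335),
    height = c(900, 600), sigma = c(18, 18)), noiseFraction = 0)
  writeEEM(shifted, file.path(dir, "eem_trt.csv"))
  dir
}

study_config <- function(dir) {
  list(
    seed = 1,
    constants = list(tau0 = 1e-8, K2 = 2 / 3, N = 1.34, phi = 0.15),
    ligands = list(LIG1 = list(
      titrations = lapply(c(293, 298, 303), function(Tk) list(
        file = file.path(dir, paste0("titration_", Tk, ".csv")),
        temperature = Tk)),
      emission_file = file.path(dir, "emission.csv"),
      absorption_file = file.path(dir, "absorption.csv"),
      absorption_concentration = 1e-5,
      fret_F = 870, fret_F0 = 1000,
      formula = "C4F9O3S", binding_energy_kcal = -5.196,
      ftir_file = file.path(dir, "ftir.csv"),
      eem_reference_file = file.path(dir, "eem_ref.csv"),
      eem_treated_file = file.path(dir, "eem_trt.csv"))))
}

test_that("a full synthetic study populates every block", {
  dir <- make_study_dir()
  rep <- runFullStudy(study_config(dir), quiet = TRUE)
  expect_s4_class(rep, "StudyReport")
  blk <- rep@ligands$LIG1
  expect_null(blk$errors)
  expect_named(blk$quenching, c("293", "298", "303"))
  expect_equal(blk$quenching[["293"]]$Ka, 1.6e6, tolerance = 1e-5)
  expect_equal(blk$quenching[["293"]]$mechanism, "static")
  expect_gt(blk$thermo$delta_H_kJ, 0)
  expect_equal(blk$thermo$force_class, "hydrophobic")
  expect_equal(blk$fret$E, 0.13)
  expect_true(blk$fret$valid)
  expect_equal(blk$ligand_efficiency$n_heavy, 17)
  expect_equal(round(blk$ligand_efficiency$LE, 3), 0.306)
  expect_equal(sum(unlist(blk$secondary_structure$percent)), 100,
               tolerance = 1e-3)
  expect_equal(blk$eem_shifts$delta_emission, c(-5, -5))
  expect_equal(length(rep@provenance$file_md5), 8)
})

test_that("a subset configuration runs only its stages", {
  dir <- make_study_dir()
  cfg <- list(ligands = list(L = list(
    titrations = list(list(file = file.path(dir, "titration_298.csv"),
                           temperature = 298)))))
  expect_message(rep <- runFullStudy(cfg), "skipped")
  blk <- rep@ligands$L
  expect_named(blk$quenching, "298")
  expect_null(blk$fret)
  expect_null(blk$thermo)
  expect_null(blk$secondary_structure)
})

test_that("a missing input file is annotated, named, and non-fatal", {
  cfg <- list(ligands = list(L = list(
    titrations = list(list(file = "/nonexistent/titr.csv",
                           temperature = 298)))))
  expect_warning(rep <- runFullStudy(cfg, quiet = TRUE),
                 "nonexistent/titr.csv")
  expect_match(rep@ligands$L$errors$quenching, "titr.csv")
})

test_that("reports are byte-identical across reruns and re-parse losslessly", {
  dir <- make_study_dir()
  cfg <- study_config(dir)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  writeStudyReport(runFullStudy(cfg, quiet = TRUE), f1)
  writeStudyReport(runFullStudy(cfg, quiet = TRUE), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  parsed <- readStudyReport(f1)
  blk <- parsed$ligands$LIG1
  expect_equal(blk$fret$R0_nm,
               runFullStudy(cfg, quiet = TRUE)@ligands$LIG1$fret$R0_nm,
               tolerance = 1e-12)
  expect_equal(blk$quenching[["293"]]$Ka, 1.6e6, tolerance = 1e-5)

  # plain-text rendering also works
  ftxt <- tempfile(fileext = ".txt")
  writeStudyReport(runFullStudy(cfg, quiet = TRUE), ftxt, format = "text")
  expect_true(any(grepl("LIG1", readLines(ftxt))))
})

test_that("a YAML configuration file drives the same study", {
  dir <- make_study_dir()
  cfg <- study_config(dir)
  yf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yf)
  rep <- runFullStudy(yf, quiet = TRUE)
  expect_equal(rep@ligands$LIG1$ligand_efficiency$n_heavy, 17)
  expect_error(runFullStudy(tempfile(fileext = ".yaml")), "not found")
})
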