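Package: specbind
Title: Spectroscopic Analysis of Protein-Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising small-molecule binding to proteins from
    steady-state spectroscopy. Implements Stern-Volmer and double-logarithm
    fluorescence quenching analysis with static/dynamic mechanism
    classification, Forster resonance energy transfer (FRET) distance
    determination from the spectral overlap integral, van't Hoff
    thermodynamics with binding-force classification, ligand efficiency from
    docking binding energies, amide-I band deconvolution of FTIR spectra into
    secondary-structure fractions, and excitation-emission matrix (EEM)
    scatter masking, peak picking and shift detection. Includes
    synthetic-data generators with known ground truth for every input class,
    and a full-study runner that collates all derived constants into a
    structured report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
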