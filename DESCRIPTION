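Package: bbbperm
Title: Blood-Brain Barrier Permeation Modelling from Biomimetic
    Chromatography, QSAR, Bioassay Calibration and Umbrella Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the computational chain used to assess the
    central-nervous-system potential of small molecules such as oleanolic
    acid: retention-factor extrapolation on membrane-like HPLC phases
    (Soczewinski-Wachtmeister fits), a blood-brain distribution (logBB)
    QSAR with backward-elimination model building, leave-ten-out
    cross-validation and leverage-based applicability domain, IC50
    calibration for TLC-bioautography and MTT viability assays,
    distance-based ligand-protein contact classification on PDB
    structures, and 1D umbrella-sampling free-energy profiles via the
    weighted histogram analysis method with Bayesian-bootstrap errors.
    Seeded synthetic-data generators emulate every input so the whole
    pipeline is exercisable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
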