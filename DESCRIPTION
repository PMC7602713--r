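Package: adaptsig
Title: Sequence, Structure and Flexibility Signatures of Extremophilic
    Protein Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative profiling of halophilic and psychrophilic
    adaptation signatures in protein sequences, crystal structures and
    molecular-dynamics trajectories. Computes residue-class composition,
    grand average hydropathy, isoelectric point and molar extinction
    coefficients from sequences; Shrake-Rupley solvent-accessible surface
    area, relative-accessibility surface classification, hydrogen-bond and
    salt-bridge enumeration, simplified Kabsch-Sander secondary structure
    and oligomer interface burial from coordinates; and Kabsch-superposition
    RMSD series, temperature-regression thermal-sensitivity slopes,
    per-residue RMSF and delta-RMSF significance flags from multi-model
    trajectories. Includes a synthetic-data generator that plants contacts,
    burial and temperature-dependent fluctuations with known ground truth so
    the whole pipeline is testable offline, plus a comparison driver that
    aggregates metrics over organism groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
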