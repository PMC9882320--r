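Package: smcoloc
Title: Single-Molecule TIRF Colocalization and Residence-Lifetime Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for colocalization single-molecule
    spectroscopy (CoSMoS) assays of de novo centromeric nucleosome
    assembly: drift correction of multi-channel TIRF image stacks,
    template-spot detection, z-normalized intensity trace extraction,
    ON/OFF pulse calling with right-censoring annotation, ternary
    residence partitioning and off-rate estimation, Kaplan-Meier survival
    analysis with log-rank comparisons, endpoint colocalization counting,
    photobleaching step counting, and homopolymeric A/T run statistics for
    centromeric CDEII sequences.  Includes a synthetic-data generator
    (two-state Markov binding kinetics, Gaussian-PSF movie rendering with
    shot and read noise, stage drift, photobleaching, and CDEII-like
    sequence synthesis) that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    tiff,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
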