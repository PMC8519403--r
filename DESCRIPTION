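Package: famchar
Title: Gene-Family Characterization Toolkit for bHLH-Style Domain Families
Version: 0.1.0
Authors@R:
    person("famchar", "developers", email = "famchar@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide characterization of a
    transcription-factor gene family, built around the basic helix-loop-helix
    (bHLH) domain. Locates domains with a position-specific scoring matrix,
    maps them onto a fixed 61-position reference frame, calls per-position
    consensus conservation, classifies DNA-binding capability (G-box,
    non-G-box E-box, non-E-box, non-DNA-binding) by basic-region residue
    rules, computes ProtParam-style physicochemical panels (molecular weight,
    isoelectric point, GRAVY, instability and aliphatic indices), detects
    tandem gene duplications from chromosome coordinates, estimates Ka/Ks by
    the Nei-Gojobori (1986) method with Jukes-Cantor correction and dates
    divergence with a molecular clock, screens FPKM expression matrices for
    effective expression, tissue specificity and cold-responsive fold
    changes, computes 2^-ddCt qPCR relative expression, and scans promoters
    for IUPAC cis-element motifs. A synthetic-data generator with planted
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
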