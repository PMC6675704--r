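Package: pepscreen
Title: Peptide-Microarray Autoantibody Serology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for peptide-microarray serological screening
    of autoantibodies against a tiled protein antigen. Decomposes an antigen
    into overlapping peptides, quantifies spot-level signal-to-noise ratios
    against blank-spot background, selects per-peptide seropositivity
    cut-offs by maximizing the case-control positive-rate difference,
    compares groups with Fisher's exact test under Bonferroni correction,
    tracks longitudinal seroreversion and rebound, associates serostatus
    with immunohistochemistry calls via the Spearman/phi coefficient, and
    models recurrence-free survival with Kaplan-Meier curves, log-rank tests
    and Cox regression with forward selection. Includes a seeded synthetic
    cohort generator emulating the case-control study design for fully
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
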