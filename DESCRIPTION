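Package: cntdisp
Title: QSPR Modeling of Carbon Nanotube Dispersibility in Organic Solvents
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative structure-property (QSPR) modeling of single-walled
    carbon nanotube dispersibility in organic solvents. Computes topological
    descriptors on hydrogen-depleted molecular graphs (self-returning walk
    counts, ramification index, average valence connectivity, bond-order
    weighted path counts, Broto-Moreau mass autocorrelation), performs
    genetic-algorithm variable selection for multiple linear regression with
    full fit and leave-one-out statistics (R2, s, F, PRESS, Q2, SPRESS, SDEP),
    and validates models externally with Roy's rm2 metrics. Ships a packaged
    29-solvent dispersibility dataset with a reference descriptor table, and
    synthetic-data generators (random molecular graphs, sparse linear
    descriptor datasets) so every pipeline stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
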