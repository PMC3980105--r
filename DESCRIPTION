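Package: rcsqtl
Title: Mixed-Model QTL Mapping with Bootstrap Genome-Wide Correction for
    Recombinant Congenic Strains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative trait locus (QTL) mapping for panels of recombinant
    congenic strains (RCS). Fits a linear mixed model with a strain-level
    polygenic random effect whose covariance is proportional to a marker-based
    kinship matrix, scans the genome marker-by-marker with a whitened
    major-gene regression, and computes genome-wide corrected p-values by a
    max-statistic residual bootstrap built on leverage-adjusted whitened
    residuals. A naive per-marker regression scan with a raw-phenotype
    bootstrap is included for comparison, together with an RCS panel and
    phenotype simulator and a driver for type-I-error simulation studies that
    quantify how badly the naive analysis inflates the genome-wide false
    positive rate when the polygenic term is ignored.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
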