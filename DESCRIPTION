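Package: driftscan
Title: Selection-Signature Scanning in Structured Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting selection signatures from SNP-array genotypes
    of structured populations such as livestock breeds and farm lines. Reads
    and writes PLINK 1 binary genotype sets, applies quality-control filters,
    computes per-population allele frequencies, builds the VanRaden genomic
    relationship matrix with SVD-based structure summaries, estimates f2 and
    outgroup-f3 statistics with block-jackknife standard errors, scans for
    selection with Weir-Cockerham FST (sliding-window smoothing and
    95th-quantile region calling) and the kinship-corrected FLK test with
    Storey q-value FDR control, and overlaps called regions with gene/QTL
    annotation tables for Fisher-exact enrichment. A Balding-Nichols pure-drift
    genotype simulator with known ground truth makes every stage testable
    without real data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
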