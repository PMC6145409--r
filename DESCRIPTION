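Package: introscan
Title: Sliding-Window Introgression Scans with Coalescent Null Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-scale characterization of introgression in young
    adaptive radiations from multi-sample VCFs: genome-wide four-population
    f4 tests with delete-one-block jackknife standard errors, ABBA-BABA D and
    fd statistics in sliding windows, per-window nucleotide diversity (pi)
    and divergence (Dxy), a structured-coalescent simulator used both to
    calibrate fd significance thresholds under a no-migration null and to
    generate synthetic scenario datasets (no gene flow, secondary admixture
    pulse, ancestral hybrid swarm) with known introgressed windows,
    neighbor-joining topology painting of genomic windows, and
    candidate-region merging and classification into private, subclade-shared
    and clade-shared categories with hybrid-swarm and selective-sweep flags.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
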