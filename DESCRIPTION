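Package: vdpower
Title: Variety Discrimination Power Appraisal of Molecular Marker Loci
    Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Appraises the ability of molecular-marker loci combinations
    (SSR or SNP panels) to distinguish plant varieties. Implements the
    variety discrimination power (VDP) framework: pairwise genotype
    differencing over overlapping non-missing loci, variety-threshold
    classification, transitive (discrimination-chain) grouping of samples
    into repeated groups, and four appraisal statistics - probability-based
    VDP, comparison-based VDP, ratio-based VDP, and the total probability
    of discrimination power (TDP). Includes generators for benchmark
    populations with gradient variety difference degree, per-sample
    missing-data injection, nested locus subsets, and a harness for
    sensitivity curves, threshold sweeps, and missing-data stability
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
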