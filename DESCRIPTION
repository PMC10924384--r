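Package: tlegene
Title: Transfer Learning for eGene Identification from Auxiliary eQTL
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multilocus eGene identification that transfers cis-SNP effect
    estimates from an auxiliary eQTL study into a target study. The target
    model combines a fixed-effect burden of auxiliary effects with a
    variance component for direct SNP effects; the two score statistics are
    decorrelated so they are asymptotically independent, combined by
    optimally weighted, adaptively weighted and Fisher combinations, and
    aggregated into an omnibus test with the harmonic mean p-value
    calibrated against the Landau distribution. Includes genotype quality
    control, allele harmonization between studies, a linkage-disequilibrium
    aware genotype simulator, type I error and power evaluation, a per-gene
    scan with multiple-testing adjustment, the single-SNP scan used for
    comparison, and effect-correlation and detection-rate analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
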