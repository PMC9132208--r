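Package: svaduplicon
Title: Structural Inference for Retrotransposon-Mediated Segmental Duplications
Version: 0.1.0
Authors@R: person("Core", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes the structural signatures left by
    retrotransposon-mediated mobilization of segmental duplications:
    target-site duplications of L1-mediated insertions, breakpoint
    junction microhomology, clustering of independent duplication
    breakpoints and their repeat-overlap census, diagnostic-site
    partitioning and split-tree detection of inter-element recombination,
    median-joining haplotype networks with external rooting, subfamily
    chimera segmentation with circular-intermediate signature calling,
    and a genome scanner for duplications flanked by large direct
    repeats. Ships a seeded synthetic-genome simulator that plants every
    one of these structures with a machine-readable truth ledger, so the
    whole pipeline is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
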