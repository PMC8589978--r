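Package: ovipop
Title: Ancient Sheep Population Genomics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for ancient-DNA population genomics
    of domestic sheep: postmortem-damage profiling and authentication of
    ancient reads, pseudohaploid genotype calling against a SNP panel,
    outgroup-f3 and D-statistics with weighted block-jackknife standard
    errors, smartpca-style PCA with least-squares projection of low-coverage
    samples, coverage-based molecular sex determination with a loess autosomal
    expectation, and mitochondrial haplogroup classification from diagnostic
    control-region sites with exact frequency statistics. A synthetic-data
    module generates drifted allele frequencies on a population tree, damaged
    short-fragment reads on a miniature reference, and replicated
    control-region fragments, so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    seqinr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
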