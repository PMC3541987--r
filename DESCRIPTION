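Package: aupdscan
Title: Detection and Cohort Analysis of Acquired Uniparental Disomy from SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide mapping of acquired uniparental disomy (copy-neutral
    loss of heterozygosity) in tumor SNP-array cohorts. Provides a
    distance-aware two-state hidden Markov model that segments per-chromosome
    genotype-call sequences into retained-heterozygosity and UPD states, a
    copy-neutrality filter on log2 intensity ratios, a breakpoint-based
    taxonomy of called segments (whole-chromosome, telomeric, centromeric),
    per-subtype cytoband and chromosome-arm recurrence maps, rank-based group
    comparisons of aUPD burden, and a seeded synthetic SNP-array cohort
    generator with mechanism-labelled planted events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    GenomicRanges,
    IRanges,
    knitr
Config/testthat/edition: 3
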