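Package: insmeth
Title: Case-Control Analysis of CpG Methylation in the Proximal INS Promoter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the case-control analysis of percent methylation at
    the seven CpG sites of the proximal insulin (INS) gene promoter measured
    by bisulfite pyrosequencing. Provides a Gaussian-copula synthetic cohort
    generator calibrated to published type 1 and type 2 diabetes cohort
    summaries (with linkage-disequilibrium genotype simulation and additive
    cis-genotype methylation effects), a control-reference hypomethylation
    classifier using the mean minus two standard deviations rule, multi-CpG
    disease-signature detection, rank-based case-control and
    genotype-methylation association statistics, exact contingency tests,
    and summary reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    mvtnorm,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
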