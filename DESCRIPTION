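Package: methcycle
Title: DNA Methylation Turnover Analysis from 5-mC and 5-hmC Site Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of DNA methylation turnover from per-CpG
    5-methylcytosine and 5-hydroxymethylcytosine call tables.
    Aggregates site-level modification calls over chromatin-state
    annotations, screens annotation-level methylation for
    mutation-status effects with linear models and
    Benjamini-Hochberg correction, partitions CpG sites into hyper-
    and hypomethylated loci relative to the sample's own regional
    average, scores transcription-factor binding sites for
    hypermethylation burden, and estimates the rates of a
    three-state methylation/demethylation cycle (C -> 5-mC -> 5-hmC
    -> C) from the observed equilibrium base proportions.  A
    synthetic-cohort generator reproduces the statistical structure
    of nanopore-derived methylation call data so every stage is
    testable without controlled-access inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    deSolve,
    GenomicRanges,
    IRanges,
    S4Vectors,
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
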