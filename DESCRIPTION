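Package: synbreak
Title: Synteny Blocks, Replichore Bias and Rearrangement Rates in Bacterial Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects syntenic core-gene blocks between closely related bacterial
    genomes, classifies rearrangements into inversions and translocations,
    localizes them relative to the origin and terminus of replication inferred
    from cumulative GC skew, converts block counts into rearrangement-event
    estimates through a simulation-calibrated quadratic model, computes the
    B_cs rearrangement rate per substitution, and tests COG functional
    enrichment of rearranged blocks. Includes a synthetic-species generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
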