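Package: vesselmix
Title: Mixture-Aware Analysis of Brain Microvessel Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing laser-capture-microdissected brain
    microvessel RNA-seq alongside matched whole-brain samples: length- and
    depth-normalised expression (FPKM/TPM), estimation of the
    pericyte/endothelial composition of bulk microvessel samples by scanning
    convex blends of reference single-cell profiles, a simplified paired
    negative-binomial Wald test with Benjamini-Hochberg adjustment,
    homology-aware mouse-human expression comparison with reverse-calculated
    pseudo-counts, subtractive identification of putative pericyte markers,
    pre-ranked gene-set enrichment, and a synthetic-study generator for
    validating every stage against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
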