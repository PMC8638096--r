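Package: msnstat
Title: Adaptive Mutation-Specific Negative Status Calling for Multi-Sample
    Sequencing Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes "negative" from "unknown" somatic mutation statuses
    when the same mutation is examined across multiple related next-generation
    sequencing samples (multi-site biopsies, serial liquid biopsies, paired
    platform runs of the same cell). Implements the adaptive mutation-specific
    negative (MSN) rule, which labels a non-positive sample negative only when
    Fisher's exact test on mutant/wildtype read counts rejects equality of
    variant allele frequency against every known positive sample, alongside the
    conventional universal-minimum-coverage (UMC) baseline. Includes a
    count-level read simulator for benchmarking the two rules across tumor-cell
    fractions, a paired-platform concordance evaluator, tab-separated readers
    and writers for count, status and pairing tables, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
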