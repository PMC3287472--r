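Package: clipsv
Title: Structural Variant Detection from Soft-Clipped Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deletions, inversions, tandem duplications, insertions and
    translocations with single-base resolution from the soft-clipping
    information in SAM alignments of paired-end short reads. Per-read
    breakpoints derived from terminal soft-clip CIGAR operations are
    clustered, the clipped fragments are re-aligned inside reference windows
    excised around each breakpoint cluster, and the placement geometry of
    each fragment relative to its anchoring breakpoint is translated into a
    typed structural variant call with a balance-sensitive reliability
    score. The package also ships a structural-variant and paired-end read
    simulator, a deterministic seed-and-extend read mapper for fully
    self-contained test data, and discovery-rate / true-call-rate
    benchmarking of a callset against a simulated truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
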