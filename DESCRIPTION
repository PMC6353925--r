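Package: hitcover
Title: Multi-Hit Gene Combinations by Weighted Set Cover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers combinations of genes whose joint protein-altering
    mutation distinguishes tumor from normal samples, by mapping the search
    to a weighted set cover problem and solving it with a greedy
    approximation. Includes MAF-dialect parsing and binary mutation-matrix
    construction, train/test evaluation with Wilson score confidence
    intervals, post-hoc combination analyses (gene-pair correlation,
    occurrence and overlap statistics, chromosomal co-location,
    tumor-versus-normal locus contrast), and a synthetic-cohort generator
    with planted combinations for end-to-end testing without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
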