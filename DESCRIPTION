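Package: motudelim
Title: MOTU Delimitation and Congruence Analysis for DNA Barcode Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species delimitation from aligned COI DNA barcode
    libraries: Kimura 2-parameter and JC69 pairwise distances with pairwise
    deletion, neighbor-joining trees, Automatic Barcode Gap Discovery (ABGD),
    Poisson Tree Processes (maximum-likelihood and Bayesian flavors), a
    BIN-style single-linkage clustering surrogate, and a congruence layer that
    combines distance summaries, nearest-neighbor distances and the method
    partitions into per-morphospecies verdicts (cryptic candidate, new MOTU,
    assignment to a nominal species, misidentification/hybrid suspect).
    Includes a sequence simulator with known truth for end-to-end validation
    and fixtures for a worked Neotropical freshwater-fish survey example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
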