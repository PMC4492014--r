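Package: unifracnull
Title: UniFrac Distances and Null-Model Significance Tests on Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes unweighted and weighted (raw and normalized) UniFrac
    phylogenetic beta-diversity distances between microbial community samples,
    and Monte Carlo significance tests with explicitly selectable null models:
    sequence-level tip permutation on expanded trees (one tip per sequence
    occurrence), OTU-level tip permutation on collapsed trees (one tip per OTU
    with counts), per-tip label swapping, and the parsimony P test that
    randomizes tree topology while holding sample labels constant. Includes
    exact enumeration of small permutation nulls, conversion between the
    expanded and collapsed tree encodings, and a synthetic-data module for
    calibration and null-model comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
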