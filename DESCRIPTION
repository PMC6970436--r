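Package: triomed
Title: eQTL Mediation Analysis with Efficient Permutation Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests the mediation effect of a cis-eGene on a trans-eGene for
    eQTL trios (variant L, cis-gene C, trans-gene T) with linear models and
    within-genotype-group permutation testing. Implements a fixed permutation
    scheme, an adaptive early-stopping scheme, and a generalized Pareto
    distribution (GPD) approximation of the null tail that estimates p-values
    below the empirical resolution floor, together with fixed and per-trio
    adaptive confounder adjustment from an expression principal-component
    pool, and Storey-Tibshirani q-values across gene pairs. Includes a
    synthetic-data generator with known mediation structure for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
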