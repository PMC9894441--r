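Package: genotrend
Title: Trend Tests for Case-Control Genotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cochran-Armitage and Jonckheere-Terpstra trend tests for
    2x3 case-control genotype contingency tables at a diallelic marker,
    with tie-corrected null moments for the Jonckheere-Terpstra statistic.
    Includes a penetrance-based genetic-model parameterization on the
    dominant-additive-recessive arc, trinomial Monte-Carlo power
    simulation, theoretical comparison of the two statistics on expected
    genotype tables, an exact Hardy-Weinberg equilibrium test, and the
    allelic association test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
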