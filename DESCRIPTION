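Package: triadmix
Title: Supervised Three-Way Ancestry Estimation with Balanced Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of individual genetic ancestry in a
    three-ancestral-population model (European, American Indian, African) with
    parental allele frequencies treated as fixed, known quantities. Provides
    grid maximization of the Hardy-Weinberg genotype likelihood over the
    ancestry simplex, standard errors from the inverse information matrix,
    marker-informativeness statistics (allele-frequency contrasts, the
    informativeness-for-assignment statistic, Weir-Cockerham Fst), construction
    and auditing of balanced ancestry-informative-marker panels, a synthetic
    admixed-cohort generator with known truth, and experiment harnesses that
    demonstrate the failure of unbalanced panels and quantify how standard
    errors shrink as markers accumulate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    optparse,
    knitr
Config/testthat/edition: 3
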