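Package: methx
Title: Methylation-Expression Integration Analysis for Tumor-Normal Array Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-methylation calling on EPIC-style beta-value matrices
    by binning beta values into low/moderate/high methylation states and testing
    the tumor-by-bin contingency table with an exact multivariate-hypergeometric
    test, with Benjamini-Hochberg correction and a median delta-beta effect
    filter; probe-context (island/shore/shelf/open-sea, promoter/body/intergenic)
    summaries; CPM-based expression filtering and a negative-binomial Wald
    differential-expression test; thyroid differentiation and BRAF-RAS
    expression signature scores; promoter and gene-body methylation-expression
    integration quadrants; a supervised enhancer-gene pairing stage; and a
    synthetic-data generator with planted ground truth that emulates a small
    tumor-versus-normal study design so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
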