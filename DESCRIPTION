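Package: equityreach
Title: Who Spreads Health-Equity Content on a Follow Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how racial health-equity content
    about colorectal cancer spreads on a follower network. Tags posts with a
    wildcard keyword dictionary, selects equity-disseminator accounts from
    organization co-following, classifies accounts as brokers (accounts whose
    followers would otherwise follow no expert), estimates follower exposure
    to equity posts under a follow-implies-see model, and computes the
    comparison statistics (pooled two-proportion z-tests, simple regressions,
    stratified proportion tables). Includes a seeded synthetic-corpus
    generator with ground-truth roles and tags for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
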