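Package: tapscreen
Title: Mixed-Contaminant Screening of Tapwater Chemistry Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-level analysis of tapwater chemistry surveys for
    mixed regulated and unregulated contaminants. Implements field-blank
    censoring and non-detect substitution, per-constituent occurrence
    summaries and MCL/MCLG exceedance screening, cumulative
    exposure-activity ratios (EAR) against ToxCast-style activity
    concentrations at cutoff, benchmark-based cumulative toxicity
    quotients (hazard index) with zero-MCLG surrogates, the EPA four-PFAS
    mixture hazard index, and one-way PERMANOVA with Kruskal-Wallis and
    Dunn post hoc group comparisons. Includes a synthetic study generator
    emulating a five-region California sampling campaign so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
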