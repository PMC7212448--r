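Package: glycoquant
Title: Site-Specific N-Glycosylation Profiling and Quantitation of
    Intact Glycopeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for site-specific N-glycosylation analysis of intact
    glycopeptide data from isobaric (TMT) labelling experiments: parsing and
    classification of N-glycan compositions (subtype, antennae, sialylation,
    core/antennary fucosylation, monoisotopic mass), census-style profiling of
    glycan-by-glycosite PSM tables, proteome-derived reporter-channel
    normalization, median-ratio glycopeptide and protein quantitation with a
    minimum-PSM filter, glycosylation-occupancy ratios, fold-change cascades
    separating commonly altered from group-unique site-specific glycans, a
    generic hypergeometric over-representation test, and a synthetic-data
    generator with planted effects and ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
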