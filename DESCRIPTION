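Package: dhesd
Title: Hierarchical Ensemble Classification for Imbalanced Social-Media
    Suicide-Risk Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting suicidal ideation from a user's social-media
    posting history when positive users are rare. Implements the deep
    hierarchical ensemble strategy (DHE-SD): the imbalanced training corpus is
    divided into balanced sub-datasets, several base text classifiers are
    trained on each, and predictions are combined by two levels of majority
    voting, which can recover the correct label even when fewer than half of
    the base classifiers are correct. Also provides the sentence-level mask
    mechanism that deletes posts sourced from semi-anonymous "tree hole"
    venues, an eight-step post-cleaning pipeline, oversampling and
    undersampling baselines, confusion-matrix metrics, desk-scale
    implementations of the TextCNN, FastText and DPCNN architectures, and a
    seeded generator of synthetic imbalanced corpora for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
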