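Package: ednacam
Title: Compare Stream eDNA Metabarcoding and Camera-Trap Surveys of
    Terrestrial Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare environmental DNA (eDNA) metabarcoding of
    stream water with camera trapping for landscape-scale terrestrial
    mammal monitoring.  Converts taxonomically assigned MOTU read-count
    tables into binary detection matrices (negative-control removal,
    similarity filtering, taxonomic-level assignment, tag-jump
    filtering), estimates per-taxon detection probabilities
    standardised to a reference sampling effort (60 L of filtered water
    or 60 camera-trap days) with Bayesian credible intervals, fits
    Poisson and binomial covariate GLMs with AICc all-subsets model
    selection, computes diversity turnover, bootstrap
    species-accumulation curves and cost-efficiency curves, and
    provides a synthetic landscape generator for end-to-end validation
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
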