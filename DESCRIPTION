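Package: freelistr
Title: Interviewer Effects in Freelist Surveys of Traditional Ecological Knowledge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify interviewer effects in whole-population
    freelist surveys of traditional ecological knowledge. Normalizes
    long-format interview records into presence/absence incidence matrices
    over species, uses, and plant-use combinations; ordinates interviews by
    non-metric multidimensional scaling (Kruskal stress-1 with weighted
    monotone regression and majorization updates); fits categorical factors
    (interviewer identity, informant demographics) to ordination locations
    with permutation significance; computes interviewer-effect vectors and
    "pull"/"tighten" statistics on the repeat-interview subset, intra- versus
    inter-informant distances, and per-interviewer novelty accounting against
    the interviewer's own reported knowledge. Ships a Rasch-style synthetic
    elicitation-process generator with tunable interviewer bias and full
    ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
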