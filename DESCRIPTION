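Package: sealforage
Title: Biologging Pipeline for Benthic Marine Predator Foraging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing archival time-depth-light and Fastloc GPS
    biologging records from benthically foraging marine predators such as
    grey seals. Provides synthetic tag-archive and GPS simulation with known
    ground truth, GPS quality and speed filtering, zero-offset correction and
    dive detection with descent/bottom/ascent phase segmentation, in-situ
    estimation of upper-water-column temperature, light attenuation and
    bio-optical chlorophyll-a, a two-state first-difference correlated random
    walk (DCRW) hidden Markov model for behavioural-state decoding with C++
    forward/Viterbi kernels, and binomial mixed models fitted by penalized
    quasi-likelihood with per-animal random intercepts and continuous-time
    AR(1) residual correlation, reported as odds-ratio tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
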