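Package: funcresp
Title: Functional Response Analysis for Prey-Depletion Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Rogers' random-predator (Type-II) functional response model
    to no-replacement predation trials by binomial maximum likelihood,
    determines functional response type by logistic regression, compares
    attack rates and handling times between experimental groups with
    Juliano's indicator-variable method, and builds non-parametric bootstrap
    confidence bands around fitted curves. Includes prey-size-selection
    statistics (depletion filtering, t-tests, one-way ANOVA with Tukey
    letters, count-to-biomass conversion) and a synthetic predation-trial
    generator emulating a factorial sex x temperature x prey-size x
    pregnancy design, so the whole pipeline is testable without external
    data. All user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
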