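Package: ectogas
Title: Temperature-Corrected Blood-Gas Reference Intervals and Predictor
    Modelling for Ectotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for point-of-care venous blood-gas panels from
    ectothermic vertebrates. Corrects analyzer (37 degrees C) pH, pO2 and pCO2
    to the animal's environmental temperature and recomputes bicarbonate and
    total CO2 through the Henderson-Hasselbalch relation; constructs seasonal
    reference intervals with Horn's outlier screening, the nonparametric
    percentile method, bootstrap confidence intervals on the interval bounds
    and WCI/WRI precision flags; ranks candidate general linear models of
    physiologic and environmental predictors by small-sample-corrected AIC
    with Akaike weights, and produces confounder-adjusted effect estimates
    with seasonal contrasts. Includes a seeded synthetic-cohort generator
    that emulates the sampling design the analysis assumes, for validation
    and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
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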