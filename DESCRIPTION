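Package: maternalsim
Title: Individual-Based Microsimulation of Maternal Mortality and Reproductive Life Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-cycle, open-population microsimulation of women's
    reproductive life courses for a configurable set of countries: fertility
    preferences and contraception, pregnancy and its losses, a five-tier
    emergency obstetric care cascade with recognition, transport and referral
    delays, cause-specific maternal mortality with underreporting, and the six
    standard maternal mortality indicators (maternal mortality ratio, pregnancy
    mortality ratio, proportional mortality ratio, maternal mortality rate,
    total maternal deaths and lifetime risk). Country parameters are resolved
    through five-level hierarchical priors (global, income group, continent,
    region, country) with damped exponential time trends. Includes a synthetic
    world generator with known ground truth, simulated-annealing calibration to
    reported-death targets, posterior predictive checks (coverage probability,
    mean absolute error, mean error) and iterative proportional fitting for
    poststratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
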