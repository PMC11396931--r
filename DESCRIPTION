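Package: oaoinvest
Title: Markov Cohort Modelling of the Lifetime Burden of Child and
    Adolescent Overweight and Obesity and the Return on Investment of
    Prevention Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic Markov cohort life-table model for estimating
    the lifetime health burden (years of life lost, years lived with
    disability, disability-adjusted life years) and economic burden
    (healthcare costs, wage and productivity losses, mortality value)
    attributable to overweight and obesity in a closed cohort of children
    and adolescents, together with the return on investment of prevention
    and treatment interventions and intervention packages. Intervention
    effects enter through potential impact fractions applied to
    cause-specific mortality and morbidity; economic streams are
    discounted to the index year. Includes a synthetic-data generator
    that produces complete, internally consistent input bundles with
    known ground truth, so the whole pipeline is testable without access
    to proprietary surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
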