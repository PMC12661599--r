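Package: fpecon
Title: Economic Modelling of Facial Palsy Telerehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the health-economic evaluation of facial palsy care
    and of telerehabilitation added to the facial neuromuscular retraining
    (fNMR) pathway. Provides a budget-impact ledger engine (line-item
    costing, inflation indexing, category subtotals and shares), a
    morbidity-burden model (time in recovery state, QALY losses from
    utility decrements, willingness-to-pay monetisation as intervals,
    societal cost add-ons), a decision-analytic cost-effectiveness engine
    (tree validation, path enumeration, rollback of expected costs and
    House-Brackmann grade effects, dominance classification, ICER and net
    monetary benefit, break-even device pricing, cohort scaling), and a
    Delphi modal-consensus scorer. Ships the published UK study tables as
    typed fixtures together with seeded synthetic-data generators so every
    stage is testable without external data.
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
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
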