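Package: rosecost
Title: Cost Modelling of Rapid On-Site Evaluation for Fine-Needle
    Aspiration Biopsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic comparison of fine-needle aspiration biopsy
    (FNAB) sampling with rapid on-site evaluation (ROSE) against fixed-pass
    sampling. Provides closed-form models of sampling performance (per-case
    adequacy, expected needle passes, expected repeat procedures) for both
    protocols, a two-period procedure-time model, a micro-costing model that
    yields the expected cost per case, a catalogue of 32 benchmark scenarios
    spanning procedure complexity, per-pass adequacy and stopping rules,
    one-way (tornado) and probabilistic (Monte Carlo) sensitivity analysis of
    the cost difference, and a stochastic per-case simulator that serves as a
    brute-force check on every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
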