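Package: ruralsim
Title: Agent-Based Microsimulation of Rural Village Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annual-step agent-based microsimulation of village population
    dynamics. Individual residents experience probabilistic death, out-migration
    (education, marriage and labour channels) and birth events under age-band
    rate schedules, with an age-structured Leslie-type projection as comparator.
    Includes a synthetic roster generator emulating observed village age/sex
    profiles, a validation workflow (age-bin aggregation, paired t-test,
    bootstrap robustness check, sex-structure comparison), counterfactual
    scenario sweeps over birth and migration rates, and reproducible run
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
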