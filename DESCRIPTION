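Package: bbmcea
Title: Cost-Utility Modelling of Blood Biomarker Triage in Alzheimer's
    Disease Diagnostic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model comparing diagnostic
    pathways for Alzheimer's disease: standard-of-care referral from primary
    care to a memory clinic, a blood amyloid biomarker used in primary care to
    gate referral, and a blood biomarker used at the memory clinic to gate
    lumbar-puncture CSF testing. A decision tree partitions a unit cohort by
    true cognitive state, amyloid status and final diagnosis; a nine-state
    annual Markov cohort model with treatment tunnel states simulates lifetime
    disease progression when a disease-modifying treatment follows
    biomarker-confirmed diagnosis. Computes discounted costs, QALYs, ICERs and
    cost-effectiveness-plane quadrants, one-way (tornado) and probabilistic
    sensitivity analyses, and a value-based price-threshold search. Registry
    derived inputs (life table, dementia-stage transitions, mortality hazard
    ratios) are emulated by clearly labelled synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
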