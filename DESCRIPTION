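Package: btacea
Title: Cost-Utility Analysis of De-Escalated Bone-Targeted Agent Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model comparing 12-weekly with 4-weekly
    administration of bone-targeted agents (denosumab, pamidronate,
    zoledronate) in patients with bone metastases, from a Canadian public
    payer perspective. Implements a two-strategy decision tree over a
    48-week horizon with symptomatic skeletal event (SSE) branches,
    weighted drug and SSE cost construction from unit-cost tables,
    EORTC QLQ-C30 to QLU-C10D utility mapping with trapezoidal QALY
    accrual, incremental cost-effectiveness ratio and incremental net
    benefit reporting, one-way deterministic sensitivity analysis
    (tornado), probabilistic sensitivity analysis by Monte Carlo sampling
    of fitted parameter distributions, and cost-effectiveness
    acceptability curves. A synthetic two-arm trial generator provides
    patient-level data with the statistical structure the analysis
    assumes, so the full pipeline is testable end-to-end.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    zoo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
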