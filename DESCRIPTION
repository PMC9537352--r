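Package: costaware
Title: Cost-Aware Feature Selection for Clinical Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Makes any risk-prediction model cost-aware. Per-feature additive
    (Shapley) importance is computed on a model fitted to all features, the
    importance-maximizing feature subset within an acquisition-cost budget is
    found by exact 0/1 knapsack optimization (with greedy, recursive-elimination
    and no-retrain alternatives, and grouped costs for panel-style acquisition),
    and a restricted model is retrained on the selected features. Includes
    cost-performance curve alignment and paired comparison, precision-targeted
    deployment extrapolation, a budget-targeted binary-search harness for
    tradeoff-parameterized learners, and a synthetic clinical-style tabular
    data generator with closed-form optimal subsets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    optparse
Config/testthat/edition: 3
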