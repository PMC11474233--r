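Package: akiplan
Title: Anesthesia Plan Risk Assessment for Postoperative Acute Kidney Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-planner recommendation of intraoperative anesthesia parameters
    to reduce the risk of acute kidney injury (AKI) after cardiac surgery. Two
    stratum-specific feed-forward regression networks map eight preoperative
    features to six anesthesia parameters: one trained on patients who developed
    postoperative AKI and one on patients who did not. A proposed anesthesia plan
    is located by its pair of standardized Euclidean distances to the two
    planners' predictions and classified as risky when it lies closer to the
    AKI-positive prototype (below the y = x line). Includes KDIGO
    serum-creatinine staging, stratified train/test splitting, gradient-boosted
    feature ranking, k-means candidate treatments with majority voting, a
    safety-margin plan recommender, and a seeded synthetic cohort generator
    calibrated to published summary statistics for testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
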