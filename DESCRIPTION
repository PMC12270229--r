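Package: iwsrisk
Title: Explainable LSTM Risk Prediction for Iatrogenic Withdrawal Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the short-term risk of iatrogenic withdrawal syndrome
    (IWS) in pediatric intensive-care patients from longitudinal electronic
    health records. Raw time-stamped vital signs, medication administrations
    and WAT-1 withdrawal assessments are aggregated into 4-hour epochs,
    imputed, min-max scaled and arranged into sliding 24-hour observation
    windows. A manually unrolled two-layer LSTM with a batch-normalized
    fully connected head is trained by backpropagation through time, its
    probabilities are recalibrated by Platt scaling, and every prediction is
    decomposed into per-feature, per-epoch relevance scores by layer-wise
    relevance propagation through the recurrent cell. Permutation-based
    importance validation and a synthetic cohort generator with a planted,
    recency-weighted risk mechanism make the full pipeline testable without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
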