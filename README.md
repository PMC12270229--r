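# iwsrisk

Explainable recurrent risk prediction for **iatrogenic withdrawal syndrome
(IWS)** in pediatric intensive care.

Children who receive opioids and sedatives for prolonged periods in the ICU
frequently develop withdrawal when those drugs are weaned. Detection today
relies on intermittent bedside scoring (WAT-1: an 11-item, 12-point scale,
score ≥ 3 indicating withdrawal). `iwsrisk` turns routinely collected EHR
streams — time-stamped vital signs, medication administrations, WAT-1
assessments, demographics — into a dynamic 4-hour-ahead risk score with a
per-feature, per-epoch explanation of every prediction. It is aimed at
clinical-informatics researchers who want a fully inspectable,
dependency-light reference implementation of the whole chain.

## What it implements

* **Feature pipeline** — timelines anchored at extubation are cut into
  half-open 4-hour epochs; per epoch: 6 vitals × {min, max, max-delta,
  mean, count} + 8 drugs × {dose rate/kg, cumulative dose/kg, previous
  epoch dose/kg, cumulative exposure duration} + 4 scalars = 66 features.
  One-epoch carry-forward imputation with patient-mean and cohort-mean
  fallbacks, [0, 1] min-max scaling fitted on the training patients,
  sliding 6-epoch observation windows labeled by the following epoch
  (any WAT-1 ≥ 3).
* **Model** — a manually unrolled, unidirectional two-layer LSTM

  `i_t = σ(W_ih^(i) x_t + W_hh^(i) h_{t−1} + b^(i))`, …,
  `c_t = f_t ⊙ c_{t−1} + i_t ⊙ c̃_t`, `h_t = o_t ⊙ tanh(c_t)`,

  with batch norm → dropout → fully connected head → sigmoid on the final
  hidden state; uniform `±1/√H` initialization; Adam + decoupled weight
  decay with hand-derived backpropagation through time; Platt scaling of
  the raw probabilities fitted on the validation split.
* **Explainer** — layer-wise relevance propagation (LRP) through the
  recurrent cell: epsilon-rule redistribution through the (batch-norm
  folded) head, hidden→cell via the output gate, magnitude-proportional
  splitting of the forget/input branches, candidate-gate-only attribution
  back to `[h_{t−1}, x_t]`, recursing backward through time and layers to
  a 6 × 66 signed relevance map per prediction.
* **Evaluation** — fixed-sensitivity operating-point tables (sensitivity
  0.70–0.95), ROC/PR curves with trapezoidal AUROC and average-precision
  AUPRC, reliability curves with expected calibration error.
* **Permutation validation** — global (trajectory-level) and
  time-epoch-specific feature permutations with full metric-block deltas
  at threshold 0.5 on raw outputs.
* **Synthetic cohort generator** — irregular vitals with configurable
  per-variable missingness, tapering per-kg dosing schedules, and WAT-1
  labels from a planted, recency-weighted logistic risk mechanism with
  stored ground truth, so every claim above is testable without clinical
  data.

## Worked example

```r
library(iwsrisk)

coh   <- generate_cohort(cohort_config(n_patients = 300, seed = 1))
ds    <- build_dataset(coh, seed = 1)          # patient-level train/val/test
model <- lstm_train(ds$train, ds$val,
                    train_config(hidden_dim = 32, max_epochs = 40,
                                 patience = 10, seed = 1))

p_raw <- predict_proba(model, ds$test)
roc_pr(p_raw, ds$test$label)$auroc
#> [1] 0.9486969

cal <- fit_platt(predict_proba(model, ds$val), ds$val$label)
metrics_at_sensitivity(apply_platt(cal, p_raw), ds$test$label, 0.80)[, 1:8]
#>   target_sensitivity threshold sensitivity precision  accuracy specificity
#> 1                0.8 0.3870894         0.8 0.8837209 0.9165868   0.9604222
#>         npv       f1
#> 1 0.9273885 0.839779

rel <- explain_windows(model, ds$test)
head(aggregate_importance(rel)$ranking, 3)
#>                    feature     signed  absolute
#> 7           heart_rate_max -0.2114552 0.2114552
#> 64 prior_withdrawal_epochs  0.2011840 0.2011840
#> 9          heart_rate_mean  0.1648715 0.1648715
```

The AUROC says how well the model separates windows that precede a
positive WAT-1 screen from those that do not; the metric row is the
operating point a clinician would get by fixing 80% sensitivity; the
signed/absolute ranking shows which inputs carried the predictions — here
heart-rate extremes and the prior withdrawal burden, two of the planted
drivers of the synthetic cohort. (At the default 500-patient study scale
the prior-withdrawal count ranks first by mean absolute window-aggregated
relevance; that recovery property is what the acceptance suite checks.)

A thin CLI over the same functions lives in `inst/cli/iwsrisk.R`
(`simulate`, `prepare`, `train`, `evaluate`, `explain`, `permute`).

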