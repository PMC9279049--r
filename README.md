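# deeppsy

Multimodal behavioral screening of student mental-health risk from routine
school logs: canteen consumption events, internet sessions, course grades
and insomnia indicators.

The package is aimed at methods researchers in digital phenotyping and
mental-health informatics who want a fully tested, reproducible
implementation of a log-based screening pipeline — from raw event tables
to a trained fusion classifier — together with the experiment harness
(paired model comparison, feature ablation, hyperparameter sweeps) needed
to characterize it. Because no student cohort can be shipped, a seeded
synthetic-cohort simulator with planted, per-channel effect sizes stands
in for the data; every number the package reports is computed on that
simulator.

## What is implemented

**Feature engineering** (one row per student):

- grade point `F = (score − 50)/10`, course quality `Q = credit · F`, and
  the aggregate `F_avg = ΣQᵢ / ΣScoreᵢ` (credit-sum denominator available
  by flag);
- dining regularity as Shannon entropy `E = −Σ pᵢ log pᵢ` of the
  meal-event distribution over breakfast/lunch/dinner/other windows;
- a dining anomaly score from k-means (k = 3, Lloyd with restarts) over
  (entropy, meals/day, window coverage):
  `M = D(x, cᵢ) · (1 − |Cᵢ|/N)` — centroid distance weighted up for small
  clusters;
- insomnia probability `P = insomnia nights / observed days`;
- internet-usage summaries (sessions/day, late-night fraction).

**Models:**

- a five-layer base CNN (conv → pool → conv → pool → fc) over day×hour
  activity grids, with learned pooling weights
  `x̂ = f(w·down(x) + b)`;
- **DeepPsy**, the fusion model: a CNN(4, 32 kernels, 3×3, same padding,
  batchnorm) + LSTM(4 units) trajectory branch over weekly activity
  grids, concatenated with a fully connected (8 → 4) branch over the
  tabular features, fused through a 4-unit layer and softmax; trained
  end to end with Adam (60 epochs, batch 4, lr 1e−3, dropout 0.5,
  class-weighted cross-entropy). All layers — convolution, pooling,
  batch normalization, LSTM, Adam — are implemented in this package
  (vectorized R over fused Rcpp/BLAS kernels) with hand-derived
  backpropagation verified against finite differences;
- a five-classifier bench (random forest, naive Bayes, gradient
  boosting, neural network, decision tree) with stratified 60/20/20
  splits, validation-F1 selection and an accuracy/precision/recall/F1/AUC
  panel.

**Experiments:** `run_comparison()` (best tabular classifier vs DeepPsy,
paired seeds), `run_ablation()` (four nested feature sets), `run_sweep()`
(kernel-count and batch-size robustness), `plot_training()` (curves with
annotated stabilization epoch).

## Worked example

```r
library(deeppsy)

cohort   <- simulate_cohort(cohort_config(seed = 1))   # 210 students, 60 days
features <- build_feature_table(cohort)
grids    <- activity_grids(cohort)                     # 210 x 9 x 7 x 24

splits <- split_data(features, seed = 1)
bench  <- run_bench(features, splits, seed = 1)
print(bench)
```

```
Classifier bench (test split):
  rf  acc 1.000  prec 1.000  rec 1.000  F1 1.000  AUC 1.000
  nb  acc 1.000  prec 1.000  rec 1.000  F1 1.000  AUC 1.000
  gb  acc 1.000  prec 1.000  rec 1.000  F1 1.000  AUC 1.000
  nn  acc 1.000  prec 1.000  rec 1.000  F1 1.000  AUC 1.000
  dt  acc 1.000  prec 1.000  rec 1.000  F1 1.000  AUC 1.000
selected: dt (validation F1, recall tiebreak)
```

With the default planted effect sizes (one baseline standard deviation on
each of the four channels) the 210-student cohort is fully separable, so
every model sits at ceiling on this split and the selection falls back to
the tie rule; accuracy is the fraction of correct test-split flags and
recall the fraction of true MD students flagged. Dial `effect_sizes` down
in `cohort_config()` for a harder cohort. Training the fusion model on the
same split:

```r
tab <- as.matrix(features[c("gpa", "dining_entropy", "anomaly_m",
                            "insomnia_p", "sessions_per_day",
                            "night_fraction")])
model <- build_deeppsy(deeppsy_spec(seed = 1), n_basic = ncol(tab),
                       n_weeks = dim(grids)[2])
fit <- train_deeppsy(model, grids, tab, as.integer(features$md) + 1L,
                     train_idx = splits$train, val_idx = splits$validation)
probs <- predict(fit$model, grids[splits$test, , , , drop = FALSE],
                 tab[splits$test, , drop = FALSE])
compute_metrics(features$md[splits$test],
                as.integer(max.col(probs) == 2), probs[, 2], "deeppsy")
```

```
    model tp fp fn tn accuracy precision recall f1 auc
1 deeppsy 12  0  0 30        1         1      1  1   1
```

A command-line front end over the same functions is installed at
`inst/cli/deeppsy-cli.R` (`simulate`, `featurize`, `bench`, `compare`,
`ablate`, `sweep`, `curves`).

The methods vignette (`vignettes/deeppsy-methods.Rmd`) documents the
models, the generator's assumptions, every defaulted parameter and the
design decisions behind ambiguous formulas.

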