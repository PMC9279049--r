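# Study-condition runs shared by several acceptance checks; computed once
# per session and memoised. Conditions: the default 210-student cohort with
# strong planted effects (standardized effect 2 on every channel) and a
# zero-effect null cohort, 10 paired seeds each.

.study_cache <- new.env(parent = emptyenv())

study_seeds <- 1:10

strong_cohort <- function() {
  simulate_cohort(cohort_config(
    effect_sizes = c(dining_irregularity = 2, late_night_use = 2,
                     grade_deficit = 2, insomnia_rate = 2),
    seed = 42))
}

null_cohort <- function() {
  simulate_cohort(cohort_config(
    effect_sizes = c(dining_irregularity = 0, late_night_use = 0,
                     grade_deficit = 0, insomnia_rate = 0),
    seed = 42))
}

study_comparison <- function() {
  if (is.null(.study_cache$comparison)) {
    .study_cache$comparison <- run_comparison(strong_cohort(),
                                              seeds = study_seeds)
  }
  .study_cache$comparison
}

study_ablation <- function() {
  if (is.null(.study_cache$ablation)) {
    .study_cache$ablation <- run_ablation(strong_cohort(), seeds = study_seeds)
  }
  .study_cache$ablation
}

# DeepPsy on the null cohort: held-out recall and predicted-positive rate
study_null_runs <- function() {
  if (is.null(.study_cache$null_runs)) {
    co <- null_cohort()
    ft <- build_feature_table(co)
    ag <- activity_grids(co)
    rows <- lapply(study_seeds, function(s) {
      splits <- split_data(ft, seed = s)
      sp <- deeppsy_spec(seed = s)
      r <- deeppsy:::.dp_run(ft, ag, splits, sp)$report
      data.frame(seed = s, recall = r$recall,
                 pred_pos = (r$tp + r$fp) / (r$tp + r$fp + r$fn + r$tn))
    })
    .study_cache$null_runs <- do.call(rbind, rows)
  }
  .study_cache$null_runs
}
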