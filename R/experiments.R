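#' Feature-ablation plan
#'
#' The four nested dataset definitions used to attribute predictive signal
#' to data sources: dataset 1 = network + performance + consumption,
#' dataset 2 = performance + consumption, dataset 3 = network + performance,
#' dataset 4 = performance only. Dataset 1 is a superset of every other and
#' dataset 4 a subset of every other.
#'
#' @return An `ablation_plan`: named list of channel vectors.
#' @export
ablation_plan <- function() {
  plan <- list(dataset1 = c("network", "performance", "consumption"),
               dataset2 = c("performance", "consumption"),
               dataset3 = c("network", "performance"),
               dataset4 = "performance")
  stopifnot(all(vapply(plan, function(d) all(d %in% plan$dataset1), logical(1))),
            all(vapply(plan, function(d) all(plan$dataset4 %in% d), logical(1))))
  structure(plan, class = "ablation_plan")
}

#' Hyperparameter sweep plan
#'
#' @param parameter name of the swept [deeppsy_spec()] field, e.g.
#'   `"conv1_kernels"` or `"batch_size"`.
#' @param values at least two values to sweep over.
#' @param seeds seeds replicated at every value (paired design).
#' @return A `sweep_plan`.
#' @export
sweep_plan <- function(parameter = "conv1_kernels",
                       values = c(2L, 4L, 8L, 16L, 32L),
                       seeds = 1:10) {
  if (length(values) < 2L) {
    stop("a sweep needs at least two values", call. = FALSE)
  }
  structure(list(parameter = parameter, values = values, seeds = seeds),
            class = "sweep_plan")
}

# tabular columns + trajectory usage implied by a channel set
.channel_design <- function(channels) {
  ch <- feature_channels()
  stopifnot(all(channels %in% names(ch)))
  list(tab_cols = unname(unlist(ch[intersect(names(ch), channels)])),
       use_trajectory = "network" %in% channels)
}

# train a DeepPsy variant on one split and return its test report
.dp_run <- function(features, grids, splits, spec,
                    channels = c("network", "performance", "consumption")) {
  des <- .channel_design(channels)
  tab <- as.matrix(features[des$tab_cols])
  y <- as.integer(features$md) + 1L
  model <- build_deeppsy(spec, n_basic = ncol(tab),
                         n_weeks = if (des$use_trajectory) dim(grids)[2] else NULL,
                         grid_dim = if (des$use_trajectory) dim(grids)[3:4] else c(7L, 24L),
                         use_trajectory = des$use_trajectory)
  fit <- train_deeppsy(model, if (des$use_trajectory) grids else NULL, tab, y,
                       train_idx = splits$train, val_idx = splits$validation)
  probs <- predict(fit$model,
                   if (des$use_trajectory) grids[splits$test, , , , drop = FALSE] else NULL,
                   tab[splits$test, , drop = FALSE])
  rep_ <- compute_metrics(features$md[splits$test],
                          as.integer(max.col(probs) == ncol(probs)),
                          probs[, ncol(probs)], model = "deeppsy")
  list(report = rep_, log = fit$log, model = fit$model)
}

#' Paired comparison: best tabular classifier vs DeepPsy
#'
#' For every seed, splits the cohort once, runs the five-classifier bench
#' and the full DeepPsy model on identical splits, and collects the paired
#' test-metric differences (DeepPsy minus baseline). A sign test summarizes
#' whether the recall differences favour one arm.
#'
#' @param cohort a `cohort`.
#' @param seeds integer vector of at least 5 seeds.
#' @param spec the [deeppsy_spec()] used for every run (its seed is replaced
#'   by the run seed).
#' @param features,grids optional precomputed [build_feature_table()] /
#'   [activity_grids()] results for the cohort.
#' @return A `comparison_result`: list with `per_seed` (data frame of paired
#'   test metrics), `medians`, and `sign_test` (the recall sign-test
#'   p-value).
#' @export
run_comparison <- function(cohort, seeds = 1:10, spec = deeppsy_spec(),
                           features = NULL, grids = NULL) {
  if (length(seeds) < 5L) stop("need at least 5 seeds", call. = FALSE)
  if (is.null(features)) features <- build_feature_table(cohort)
  if (is.null(grids)) grids <- activity_grids(cohort)
  rows <- list()
  for (s in seeds) {
    splits <- split_data(features, seed = s)
    bench <- run_bench(features, splits, seed = s)
    best <- select_classifier(bench)
    base <- bench[[best]]$test
    sp <- spec; sp$seed <- as.integer(s)
    dp <- .dp_run(features, grids, splits, sp)$report
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, baseline = best,
      base_accuracy = base$accuracy, base_recall = base$recall, base_f1 = base$f1,
      dp_accuracy = dp$accuracy, dp_recall = dp$recall, dp_f1 = dp$f1,
      d_accuracy = dp$accuracy - base$accuracy,
      d_recall = dp$recall - base$recall,
      d_f1 = dp$f1 - base$f1,
      split_signature_equal = TRUE)     # both arms consumed the same splits
  }
  per_seed <- do.call(rbind, rows)
  nz <- per_seed$d_recall[per_seed$d_recall != 0 & !is.na(per_seed$d_recall)]
  sign_p <- if (length(nz) == 0) 1 else
    stats::binom.test(sum(nz > 0), length(nz))$p.value
  structure(list(per_seed = per_seed,
                 medians = vapply(per_seed[c("base_recall", "dp_recall",
                                             "d_accuracy", "d_recall", "d_f1")],
                                  stats::median, numeric(1), na.rm = TRUE),
                 sign_test = sign_p),
            class = "comparison_result")
}

#' Feature-ablation experiment
#'
#' Retrains DeepPsy on each of the four nested channel sets of an
#' [ablation_plan()], using identical splits per seed across datasets
#' (paired design). Variants without the network channel drop the
#' trajectory branch and the network tabular columns.
#'
#' @inheritParams run_comparison
#' @param plan an [ablation_plan()].
#' @return An `ablation_result`: list with `per_run` (data frame) and
#'   `medians` (per-dataset medians of accuracy/recall/F1).
#' @export
run_ablation <- function(cohort, plan = ablation_plan(), seeds = 1:10,
                         spec = deeppsy_spec(), features = NULL, grids = NULL) {
  stopifnot(inherits(plan, "ablation_plan"))
  if (is.null(features)) features <- build_feature_table(cohort)
  if (is.null(grids)) grids <- activity_grids(cohort)
  rows <- list()
  for (s in seeds) {
    splits <- split_data(features, seed = s)
    for (ds in names(plan)) {
      sp <- spec; sp$seed <- as.integer(s)
      rep_ <- .dp_run(features, grids, splits, sp, channels = plan[[ds]])$report
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, seed = s, accuracy = rep_$accuracy,
        recall = rep_$recall, f1 = rep_$f1,
        split_signature = attr(splits, "signature"))
    }
  }
  per_run <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(split(per_run, per_run$dataset), function(d) {
    data.frame(dataset = d$dataset[1],
               accuracy = stats::median(d$accuracy, na.rm = TRUE),
               recall = stats::median(d$recall, na.rm = TRUE),
               f1 = stats::median(d$f1, na.rm = TRUE))
  }))
  rownames(med) <- NULL
  structure(list(per_run = per_run, medians = med), class = "ablation_result")
}

#' Hyperparameter robustness sweep
#'
#' Retrains the full DeepPsy model at each value of the swept parameter with
#' the same seeds and splits at every value (paired design), and tabulates
#' per-value medians and ranges of accuracy, recall and F1. The
#' `fluctuation` entry is the max - min of the per-value medians of each
#' metric across the sweep.
#'
#' @inheritParams run_comparison
#' @param plan a [sweep_plan()].
#' @return A `sweep_result`: list with `per_run`, `per_value` (median and
#'   range per swept value) and `fluctuation`.
#' @export
run_sweep <- function(cohort, plan = sweep_plan(), spec = deeppsy_spec(),
                      features = NULL, grids = NULL) {
  stopifnot(inherits(plan, "sweep_plan"))
  if (is.null(features)) features <- build_feature_table(cohort)
  if (is.null(grids)) grids <- activity_grids(cohort)
  splits_by_seed <- lapply(plan$seeds, function(s) split_data(features, seed = s))
  rows <- list()
  for (vi in seq_along(plan$values)) {
    for (si in seq_along(plan$seeds)) {
      sp <- spec
      sp[[plan$parameter]] <- plan$values[vi]
      sp$seed <- as.integer(plan$seeds[si])
      sp <- do.call(deeppsy_spec, unclass(sp))   # revalidate
      rep_ <- .dp_run(features, grids, splits_by_seed[[si]], sp)$report
      rows[[length(rows) + 1L]] <- data.frame(
        value = plan$values[vi], seed = plan$seeds[si],
        accuracy = rep_$accuracy, recall = rep_$recall, f1 = rep_$f1)
    }
  }
  per_run <- do.call(rbind, rows)
  per_value <- do.call(rbind, lapply(split(per_run, per_run$value), function(d) {
    data.frame(value = d$value[1],
               accuracy = stats::median(d$accuracy), recall = stats::median(d$recall),
               f1 = stats::median(d$f1),
               accuracy_range = diff(range(d$accuracy)),
               recall_range = diff(range(d$recall)),
               f1_range = diff(range(d$f1)))
  }))
  rownames(per_value) <- NULL
  fluct <- vapply(per_value[c("accuracy", "recall", "f1")],
                  function(v) diff(range(v)), numeric(1))
  structure(list(parameter = plan$parameter, per_run = per_run,
                 per_value = per_value, fluctuation = fluct),
            class = "sweep_result")
}

#' Stabilization epoch of a training log
#'
#' The first epoch from which the training loss varies by less than 1% of
#' its overall range (suffix range criterion); 1 for a constant log.
#'
#' @param log a `deeppsy_trainlog`.
#' @return Integer epoch.
#' @export
stabilization_epoch <- function(log) {
  loss <- log$train_loss
  rng <- max(loss) - min(loss)
  if (rng == 0) return(1L)
  n <- length(loss)
  suffix_rng <- rev(cummax(rev(loss))) - rev(cummin(rev(loss)))
  which(suffix_rng < 0.01 * rng)[1]
}

#' Plot training curves
#'
#' Writes accuracy and loss versus epoch as PNG files, annotating the
#' [stabilization_epoch()] with a vertical line.
#'
#' @param log a `deeppsy_trainlog` from [train_deeppsy()].
#' @param prefix file path prefix; `<prefix>_accuracy.png` and
#'   `<prefix>_loss.png` are written.
#' @return Invisibly, list with `files` and `stabilization_epoch`.
#' @export
plot_training <- function(log, prefix = "deeppsy") {
  if (is.null(log) || nrow(log) == 0) {
    stop("plotting error: empty training log", call. = FALSE)
  }
  stab <- stabilization_epoch(log)
  files <- paste0(prefix, c("_accuracy.png", "_loss.png"))
  cols <- list(c("train_acc", "val_acc"), c("train_loss", "val_loss"))
  ylabs <- c("accuracy", "loss")
  for (i in 1:2) {
    grDevices::png(files[i], width = 800, height = 500)
    y1 <- log[[cols[[i]][1]]]; y2 <- log[[cols[[i]][2]]]
    ylim <- range(c(y1, y2), na.rm = TRUE)
    graphics::plot(log$epoch, y1, type = "l", lwd = 2, ylim = ylim,
                   xlab = "epoch", ylab = ylabs[i],
                   main = paste("DeepPsy training", ylabs[i]))
    if (any(!is.na(y2))) graphics::lines(log$epoch, y2, lty = 2, lwd = 2)
    graphics::abline(v = stab, col = "grey40", lty = 3)
    graphics::legend("right", legend = c("train", "validation",
                                         paste0("stabilization @ ", stab)),
                     lty = c(1, 2, 3), lwd = c(2, 2, 1), bty = "n")
    grDevices::dev.off()
  }
  invisible(list(files = files, stabilization_epoch = stab))
}
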