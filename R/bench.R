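#' Stratified train/validation/test split
#'
#' Partitions the rows of a feature table into disjoint train, validation
#' and test sets, stratified by the binary label so each split's class
#' proportions track the global ones. Overall split sizes are the
#' largest-remainder rounding of `n * fractions`; per-class allocations are
#' rounded the same way and then reconciled with the overall sizes. The
#' shuffle is controlled by `seed`, so identical calls give identical
#' partitions.
#'
#' @param table data frame with an `md` column (0/1), or any length-`n`
#'   labelled object via `labels`.
#' @param fractions length-3 positive fractions (train, validation, test)
#'   summing to 1.
#' @param seed integer seed.
#' @param labels optional binary label vector overriding `table$md`.
#' @return A `data_split`: list of integer index vectors `train`,
#'   `validation`, `test`, with a `signature` attribute identifying the
#'   partition.
#' @export
split_data <- function(table, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                       labels = NULL) {
  if (is.null(labels)) labels <- table$md
  n <- length(labels)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be 3 positive values summing to 1", call. = FALSE)
  }
  lr <- function(quota) {            # largest-remainder rounding, keeps sum
    fl <- floor(quota)
    rem <- sum(round(sum(quota))) - sum(fl)
    extra <- order(quota - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1L
    as.integer(fl)
  }
  totals <- lr(n * fractions)
  classes <- sort(unique(labels))
  alloc <- t(vapply(classes, function(cl) lr(sum(labels == cl) * fractions),
                    integer(3)))
  # reconcile column sums with the overall split sizes
  for (s in 1:3) {
    while (sum(alloc[, s]) > totals[s]) {
      donor <- which.max(alloc[, s])
      short <- which(colSums(alloc)[1:3] < totals)[1]
      alloc[donor, s] <- alloc[donor, s] - 1L
      alloc[donor, short] <- alloc[donor, short] + 1L
    }
  }
  if (length(classes) < 2L) {
    stop("stratification error: need both classes to stratify", call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (ci in seq_along(classes)) {
    idx <- sample(which(labels == classes[ci]))
    k <- cumsum(alloc[ci, ])
    out$train <- c(out$train, idx[seq_len(alloc[ci, 1])])
    if (alloc[ci, 2] > 0) out$validation <- c(out$validation, idx[(k[1] + 1):k[2]])
    if (alloc[ci, 3] > 0) out$test <- c(out$test, idx[(k[2] + 1):k[3]])
  }
  out <- lapply(out, sort)
  pos <- classes[length(classes)]
  if (any(vapply(out, function(i) sum(labels[i] == pos) == 0, logical(1)))) {
    stop("stratification error: a split has zero positive-class rows", call. = FALSE)
  }
  attr(out, "signature") <- paste(unlist(lapply(out, paste, collapse = ",")),
                                  collapse = "|")
  class(out) <- "data_split"
  out
}

#' Confusion-matrix evaluation report
#'
#' Computes the screening metric panel from binary labels and predictions:
#' accuracy, precision, recall and F1 on the positive (MD) class, plus the
#' rank-based AUC `P(score_pos > score_neg) + 0.5 P(tie)` when continuous
#' scores are supplied. Undefined quantities (e.g. precision with no
#' positive predictions, AUC with a single class) are `NA`.
#'
#' @param labels binary 0/1 vector (1 = MD).
#' @param predictions binary 0/1 vector of the same length.
#' @param scores optional numeric scores for AUC (higher = more MD-like).
#' @param model optional model name recorded in the report.
#' @return An `eval_report`: one-row data frame with counts and metrics.
#' @export
compute_metrics <- function(labels, predictions, scores = NULL, model = "") {
  stopifnot(length(labels) == length(predictions))
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  accuracy <- (tp + tn) / length(labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  auc <- NA_real_
  if (!is.null(scores) && length(unique(labels)) == 2L) {
    r <- rank(scores)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(data.frame(model = model, tp = tp, fp = fp, fn = fn, tn = tn,
                       accuracy = accuracy, precision = precision,
                       recall = recall, f1 = f1, auc = auc,
                       stringsAsFactors = FALSE),
            class = c("eval_report", "data.frame"))
}

# ---- the five tabular classifiers ---------------------------------------

.bench_grids <- list(
  rf = expand.grid(mtry = c(1L, 2L, 3L)),
  nb = expand.grid(laplace = 0),
  gb = expand.grid(max_depth = c(2L, 3L), nrounds = c(50L, 100L)),
  nn = expand.grid(size = c(4L, 8L), decay = c(0.1, 0.01)),
  dt = expand.grid(cp = c(0.01, 0.005))
)

.fit_predict <- function(name, cfg, xtr, ytr, xte, seed) {
  set.seed(seed)
  w <- length(ytr) / (2 * pmax(tabulate(ytr + 1L, 2L), 1L))
  cw <- w[ytr + 1L]
  yf <- factor(ytr, levels = c(0, 1))
  switch(name,
    rf = {
      fit <- randomForest::randomForest(
        x = xtr, y = yf, ntree = 300L,
        mtry = min(cfg$mtry, ncol(xtr)),
        classwt = w / sum(w))
      stats::predict(fit, xte, type = "prob")[, "1"]
    },
    nb = {
      fit <- e1071::naiveBayes(x = xtr, y = yf, laplace = cfg$laplace)
      stats::predict(fit, xte, type = "raw")[, "1"]
    },
    gb = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(xtr), label = ytr)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = cfg$max_depth,
                      eta = 0.1, nthread = 1L,
                      scale_pos_weight = sum(ytr == 0) / max(sum(ytr == 1), 1)),
        data = dtr, nrounds = cfg$nrounds, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(xte)))
    },
    nn = {
      ctr <- colMeans(xtr); sc <- apply(xtr, 2, stats::sd)
      sc[!is.finite(sc) | sc == 0] <- 1
      zt <- scale(xtr, ctr, sc); ze <- scale(xte, ctr, sc)
      fit <- nnet::nnet(zt, nnet::class.ind(yf), size = cfg$size,
                        decay = cfg$decay, maxit = 300L, weights = cw,
                        softmax = TRUE, trace = FALSE)
      stats::predict(fit, ze)[, "1"]
    },
    dt = {
      d <- data.frame(xtr, .y = yf)
      fit <- rpart::rpart(.y ~ ., data = d, weights = cw,
                          method = "class",
                          control = rpart::rpart.control(cp = cfg$cp,
                                                         minsplit = 5L))
      stats::predict(fit, data.frame(xte), type = "prob")[, "1"]
    },
    stop("unknown model: ", name, call. = FALSE))
}

#' Run the five-classifier bench
#'
#' Fits random forest (`rf`), naive Bayes (`nb`), gradient boosting (`gb`),
#' a single-hidden-layer neural network (`nn`) and a decision tree (`dt`)
#' on the training split, tunes each over a small fixed hyperparameter grid
#' by validation F1 (ties broken by recall), and reports the full metric
#' panel on validation and test. Class imbalance is handled with weights
#' inversely proportional to class frequency where the model supports them.
#' A model that errors is reported with a `failed` flag and does not affect
#' the others.
#'
#' @param table feature table from [build_feature_table()] (or any data
#'   frame with the feature columns and `md`).
#' @param splits a [split_data()] partition of its rows.
#' @param models subset of `c("rf", "nb", "gb", "nn", "dt")`.
#' @param seed integer seed for the model fits.
#' @param feature_cols columns used as predictors.
#' @return A `bench_result`: list of per-model lists with `validation` and
#'   `test` [compute_metrics()] reports, plus attributes `seed` and
#'   `split_signature`.
#' @export
run_bench <- function(table, splits, models = c("rf", "nb", "gb", "nn", "dt"),
                      seed = 1L,
                      feature_cols = c("gpa", "dining_entropy", "anomaly_m",
                                       "insomnia_p", "sessions_per_day",
                                       "night_fraction")) {
  stopifnot(inherits(splits, "data_split"))
  models <- match.arg(models, several.ok = TRUE)
  x <- as.matrix(table[feature_cols])
  y <- as.integer(table$md)
  if (length(unique(y[splits$train])) < 2L) {
    stop("training split is single-class", call. = FALSE)
  }
  out <- list()
  for (mi in seq_along(models)) {
    name <- models[mi]
    grid <- .bench_grids[[name]]
    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      rep_v <- tryCatch({
        sc <- .fit_predict(name, grid[gi, , drop = FALSE],
                           x[splits$train, , drop = FALSE], y[splits$train],
                           x[splits$validation, , drop = FALSE],
                           seed = seed + 1000L * mi)
        compute_metrics(y[splits$validation], as.integer(sc >= 0.5), sc, name)
      }, error = function(e) e)
      if (inherits(rep_v, "error")) next
      key <- c(rep_v$f1, rep_v$recall)
      key[is.na(key)] <- -Inf
      if (is.null(best) || key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2])) {
        best <- list(cfg = grid[gi, , drop = FALSE], validation = rep_v, key = key)
      }
    }
    if (is.null(best)) {
      out[[name]] <- list(model = name, failed = TRUE)
      next
    }
    sc_te <- .fit_predict(name, best$cfg, x[splits$train, , drop = FALSE],
                          y[splits$train], x[splits$test, , drop = FALSE],
                          seed = seed + 1000L * mi)
    out[[name]] <- list(model = name, failed = FALSE, config = best$cfg,
                        validation = best$validation,
                        test = compute_metrics(y[splits$test],
                                               as.integer(sc_te >= 0.5),
                                               sc_te, name))
  }
  structure(out, class = "bench_result", seed = seed,
            split_signature = attr(splits, "signature"))
}

#' Select the best classifier from bench reports
#'
#' Picks the model with the highest validation F1; ties are broken by
#' higher validation recall, then lexicographically by name.
#'
#' @param reports a `bench_result` from [run_bench()].
#' @return The selected model name.
#' @export
select_classifier <- function(reports) {
  ok <- Filter(function(r) isFALSE(r$failed), reports)
  if (length(ok) == 0) stop("no successful reports", call. = FALSE)
  keys <- t(vapply(ok, function(r) {
    k <- c(r$validation$f1, r$validation$recall)
    k[is.na(k)] <- -Inf
    k
  }, numeric(2)))
  names_ <- vapply(ok, `[[`, character(1), "model")
  ord <- order(-keys[, 1], -keys[, 2], names_)
  unname(names_[ord[1]])
}

#' @export
print.bench_result <- function(x, ...) {
  cat("Classifier bench (test split):\n")
  for (r in x) {
    if (isTRUE(r$failed)) {
      cat(sprintf("  %-3s FAILED\n", r$model)); next
    }
    cat(sprintf("  %-3s acc %.3f  prec %.3f  rec %.3f  F1 %.3f  AUC %.3f\n",
                r$model, r$test$accuracy, r$test$precision, r$test$recall,
                r$test$f1, r$test$auc))
  }
  cat("selected:", select_classifier(x), "(validation F1, recall tiebreak)\n")
  invisible(x)
}
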