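test_that("stratified split has exact sizes, determinism and proportional classes", {
  labels <- rep(c(0, 1), c(147, 63))
  tab <- data.frame(md = labels)
  sp <- split_data(tab, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(sp)[c("train", "validation", "test")],
               c(train = 126L, validation = 42L, test = 42L))
  expect_equal(sort(unlist(sp)), seq_len(210), ignore_attr = TRUE)  # disjoint cover
  expect_identical(sp, split_data(tab, c(0.6, 0.2, 0.2), seed = 1))
  expect_false(identical(sp, split_data(tab, c(0.6, 0.2, 0.2), seed = 2)))
  # class proportion per split within one sample of global proportion
  for (part in sp) {
    expect_lte(abs(sum(labels[part]) - 0.3 * length(part)), 1)
  }
  expect_error(split_data(tab, c(0.5, 0.5, 0.1), seed = 1), "fractions")
  expect_error(split_data(data.frame(md = rep(0, 50)), seed = 1),
               "stratification")
})

test_that("metric panel matches hand arithmetic and degenerate conventions", {
  # TP=3 FP=1 FN=2 TN=4
  labels <- c(rep(1, 5), rep(0, 5))
  preds <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  r <- compute_metrics(labels, preds)
  expect_equal(r$tp, 3); expect_equal(r$fp, 1)
  expect_equal(r$fn, 2); expect_equal(r$tn, 4)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 / 3)
  expect_equal(r$accuracy, 0.7)
  perfect <- compute_metrics(labels, labels, scores = labels)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1", "auc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, auc = 1))
  expect_true(is.na(compute_metrics(rep(1, 4), rep(1, 4), scores = 1:4)$auc))
})

test_that("metric identities and AUC hold against brute force on random instances", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    labels <- stats::rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    preds <- stats::rbinom(n, 1, 0.5)
    scores <- round(stats::rnorm(n), 1)          # rounded to force ties
    r <- compute_metrics(labels, preds, scores)
    expect_equal(r$accuracy, (r$tp + r$tn) / n)
    if (!is.na(r$f1)) {
      expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
    }
    expect_equal(r$auc, oracle_auc(labels, scores), tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC", {
  set.seed(11)
  labels <- stats::rbinom(2000, 1, 0.5)
  scores <- stats::rnorm(2000)
  auc <- compute_metrics(labels, as.integer(scores > 0), scores)$auc
  n1 <- sum(labels); n0 <- 2000 - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("all five classifiers separate an easy cohort and rerun identically", {
  set.seed(12)
  n <- 150
  md <- rep(c(0, 1), length.out = n)
  x <- matrix(stats::rnorm(n * 6), n, 6)
  x[md == 1, 1] <- x[md == 1, 1] + 6        # far-separated channel
  tab <- data.frame(x)
  names(tab) <- c("gpa", "dining_entropy", "anomaly_m", "insomnia_p",
                  "sessions_per_day", "night_fraction")
  tab$md <- md
  sp <- split_data(tab, seed = 2)
  b <- run_bench(tab, sp, seed = 2)
  for (r in b) {
    expect_false(r$failed)
    expect_gte(r$test$accuracy, 0.95)
  }
  b2 <- run_bench(tab, sp, seed = 2)
  expect_identical(lapply(b, `[[`, "test"), lapply(b2, `[[`, "test"))
})

test_that("classifier selection maximizes validation F1 with recall tiebreak", {
  mk <- function(name, f1, recall) {
    list(model = name, failed = FALSE,
         validation = data.frame(model = name, f1 = f1, recall = recall))
  }
  one <- structure(list(dt = mk("dt", 0.7, 0.5)), class = "bench_result")
  expect_equal(select_classifier(one), "dt")
  two <- structure(list(a = mk("a", 0.69, 0.2), b = mk("b", 0.60, 0.9)),
                   class = "bench_result")
  expect_equal(select_classifier(two), "a")
  tie <- structure(list(a = mk("a", 0.6, 0.58), b = mk("b", 0.6, 0.50)),
                   class = "bench_result")
  expect_equal(select_classifier(tie), "a")
  lex <- structure(list(z = mk("z", 0.6, 0.5), c = mk("c", 0.6, 0.5)),
                   class = "bench_result")
  expect_equal(select_classifier(lex), "c")
})

test_that("label-permuted features give chance-level accuracy", {
  # under permuted labels each model's accuracy should match the chance
  # level implied by its own predicted-positive rate q: p0(1-q) + p1 q
  set.seed(13)
  excess <- sapply(1:6, function(s) {
    co <- small_cohort(seed = s, per_level = 20)
    ft <- suppressWarnings(build_feature_table(co))
    ft$md <- sample(ft$md)                        # break the association
    sp <- split_data(ft, seed = s)
    b <- run_bench(ft, sp, models = c("dt", "nb"), seed = s)
    mean(sapply(b, function(r) {
      n <- with(r$test, tp + fp + fn + tn)
      q <- with(r$test, (tp + fp) / n)
      p1 <- with(r$test, (tp + fn) / n)
      chance <- (1 - p1) * (1 - q) + p1 * q
      r$test$accuracy - chance
    }))
  })
  se <- stats::sd(excess) / sqrt(length(excess))
  expect_lt(abs(mean(excess)), max(2 * se, 0.05))
})
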