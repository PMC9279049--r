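# Shared fixtures and independent oracles used across the suite.

# small cohort used by most unit tests (kept small for speed)
small_cohort <- function(seed = 1L, effects = 1, n_days = 21L, per_level = 10L) {
  simulate_cohort(cohort_config(
    n_students = 3L * per_level, per_level = per_level,
    effect_sizes = c(dining_irregularity = effects, late_night_use = effects,
                     grade_deficit = effects, insomnia_rate = effects),
    n_days = n_days, seed = seed))
}

# reduced-size model spec for fast training in unit tests
tiny_spec <- function(seed = 1L, epochs = 5L, ...) {
  deeppsy_spec(conv1_kernels = 2L, conv2_kernels = 4L, fc_width = 4L,
               lstm_input = 8L, lstm_units = 2L, epochs = epochs,
               seed = seed, ...)
}

# direct-summation GPA oracle (explicit loop, no shared code path)
oracle_gpa <- function(score, credit, denominator = "score") {
  num <- 0; den <- 0
  for (i in seq_along(score)) {
    num <- num + credit[i] * (score[i] - 50) / 10
    den <- den + if (denominator == "score") score[i] else credit[i]
  }
  num / den
}

# entropy by direct summation
oracle_entropy <- function(p) {
  e <- 0
  for (pi in p) if (pi > 0) e <- e - pi * log(pi)
  e
}

# exhaustive k-means optimum: minimal within-cluster SSE over all k^n
# assignments (empty clusters allowed; they cannot beat the optimum)
oracle_kmeans_sse <- function(x, k) {
  n <- nrow(x)
  assign_mat <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  sq <- rowSums(x^2)
  total_sq <- assign_mat_sse <- rep(0, nrow(assign_mat))
  for (c_ in seq_len(k)) {
    mask <- assign_mat == c_
    nc <- rowSums(mask)
    contrib <- mask %*% sq
    for (j in seq_len(ncol(x))) {
      s <- mask %*% x[, j]
      contrib <- contrib - ifelse(nc > 0, s^2 / pmax(nc, 1), 0)
    }
    assign_mat_sse <- assign_mat_sse + as.vector(contrib)
  }
  min(assign_mat_sse)
}

# concordant-pair AUC with half credit for ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# position-by-position valid convolution of a single-channel grid
oracle_conv_valid <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  Ho <- nrow(x) - kh + 1L; Wo <- ncol(x) - kw + 1L
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    out[i, j] <- sum(x[i:(i + kh - 1), j:(j + kw - 1)] * k)
  }
  out
}

# central finite-difference gradient of f at x (vectorized over entries)
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# model inputs (grids + tabular matrix + integer labels) for a cohort
model_inputs <- function(cohort, features = NULL) {
  if (is.null(features)) features <- suppressWarnings(build_feature_table(cohort))
  list(features = features,
       grids = activity_grids(cohort),
       tab = as.matrix(features[c("gpa", "dining_entropy", "anomaly_m",
                                  "insomnia_p", "sessions_per_day",
                                  "night_fraction")]),
       y = as.integer(features$md) + 1L)
}
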