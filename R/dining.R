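#' Daily meal windows
#'
#' The canonical time-interval set used for dining features: breakfast
#' 06:00--09:00, lunch 11:00--14:00, dinner 17:00--20:00, and an `other`
#' catch-all for events outside every canonical window (irregular eating).
#' Times are minutes after midnight; intervals are half-open `[start, end)`.
#'
#' @return Data frame with columns `window`, `start`, `end` (`other` has
#'   `NA` bounds).
#' @export
meal_windows <- function() {
  data.frame(window = c("breakfast", "lunch", "dinner", "other"),
             start = c(360, 660, 1020, NA),
             end = c(540, 840, 1200, NA),
             stringsAsFactors = FALSE)
}

.assign_window <- function(minute, windows = meal_windows()) {
  w <- windows[!is.na(windows$start), , drop = FALSE]
  out <- rep("other", length(minute))
  for (i in seq_len(nrow(w))) {
    out[minute >= w$start[i] & minute < w$end[i]] <- w$window[i]
  }
  factor(out, levels = windows$window)
}

#' Distribution of meal events over the daily windows
#'
#' Counts one student's meal events per time window and normalizes to a
#' probability vector `P(T = t_i) = n_i / sum(n_i)`.
#'
#' @param minutes meal-event times (minutes after midnight) for one student.
#' @param windows interval set, as from [meal_windows()].
#' @return Named probability vector over the windows, summing to 1. With
#'   zero events an all-`NA` vector with attribute `empty = TRUE` is
#'   returned (entropy undefined; callers treat it as missing data).
#' @export
dining_distribution <- function(minutes, windows = meal_windows()) {
  if (length(minutes) == 0) {
    out <- stats::setNames(rep(NA_real_, nrow(windows)), windows$window)
    attr(out, "empty") <- TRUE
    return(out)
  }
  counts <- table(.assign_window(minutes, windows))
  stats::setNames(as.vector(counts) / sum(counts), names(counts))
}

#' Shannon entropy of a dining distribution
#'
#' `E = -sum(p * log(p))` in natural log, with `p = 0` terms contributing 0.
#' `E` is 0 for a degenerate distribution and `log(n)` for the uniform one
#' over `n` windows; low entropy means regular eating.
#'
#' @param p probability vector summing to 1.
#' @return Non-negative entropy in nats.
#' @export
dining_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("validation error: p must be a probability vector summing to 1", call. = FALSE)
  }
  pp <- p[p > 0]
  -sum(pp * log(pp))
}

#' Per-student dining feature matrix
#'
#' Builds the vector clustered by [cluster_dining()] for every student:
#' dining entropy, meals per day, and mean daily coverage of the three
#' canonical windows (the fraction of breakfast/lunch/dinner windows with at
#' least one event, averaged over days). Students with no meal events get a
#' zero row flagged in the `empty` attribute.
#'
#' @param meals cleaned meal log (`student_id`, `day`, `minute`).
#' @param student_ids the full roster, fixing row order.
#' @param n_days number of observed days.
#' @return Numeric matrix with rows per student and columns
#'   `entropy`, `meals_per_day`, `window_coverage`; attribute `empty` marks
#'   students without events.
#' @export
dining_feature_matrix <- function(meals, student_ids, n_days) {
  win <- .assign_window(meals$minute)
  ent <- mpd <- cov <- stats::setNames(numeric(length(student_ids)), student_ids)
  empty <- stats::setNames(rep(TRUE, length(student_ids)), student_ids)
  by_student <- split(seq_len(nrow(meals)), meals$student_id)
  for (sid in names(by_student)) {
    idx <- by_student[[sid]]
    p <- dining_distribution(meals$minute[idx])
    ent[sid] <- dining_entropy(p)
    mpd[sid] <- length(idx) / n_days
    canon <- win[idx] != "other"
    hit <- unique(data.frame(day = meals$day[idx][canon],
                             w = as.character(win[idx][canon])))
    cov[sid] <- nrow(hit) / (3 * n_days)
    empty[sid] <- FALSE
  }
  out <- cbind(entropy = ent, meals_per_day = mpd, window_coverage = cov)
  rownames(out) <- student_ids
  attr(out, "empty") <- empty
  out
}

#' K-means clustering of dining behavior
#'
#' Partitions students into `k` dining-behavior groups (good / poor / sparse
#' regularity) with Lloyd's algorithm, restarted `n_restarts` times from
#' random initial centers and keeping the solution with the smallest
#' within-cluster sum of squares. Features are standardized to zero mean and
#' unit variance before clustering unless `standardize = FALSE`.
#'
#' @param x numeric matrix, one row per student.
#' @param k number of clusters (default 3).
#' @param seed integer seed; fixes the restarts, hence the result.
#' @param n_restarts number of random restarts.
#' @param standardize standardize columns before clustering?
#' @return A `dining_clustering` object: list with `assignments` (integer
#'   per row), `centers`, `sizes`, `sse` (total within-cluster sum of
#'   squares in the clustered space), and the scaling used.
#' @export
cluster_dining <- function(x, k = 3L, seed = 1L, n_restarts = 25L,
                           standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < k) {
    stop("clustering error: fewer points (", nrow(x), ") than clusters (", k, ")",
         call. = FALSE)
  }
  center <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scale_ <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale_, "/")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- z[sample.int(nrow(z), k), , drop = FALSE]
    if (anyDuplicated(init)) next
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(z, centers = init, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$cluster)) < k) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) {
    # all random restarts collapsed (e.g. heavily duplicated points);
    # fall back to the default initialisation strategy
    best <- suppressWarnings(stats::kmeans(z, centers = k, iter.max = 100L,
                                           nstart = n_restarts))
  }
  structure(list(assignments = unname(best$cluster),
                 centers = best$centers,
                 sizes = unname(best$size),
                 sse = best$tot.withinss,
                 feature_center = center,
                 feature_scale = scale_),
            class = "dining_clustering")
}

#' @export
print.dining_clustering <- function(x, ...) {
  cat("Dining-behavior clustering: k =", nrow(x$centers),
      "| sizes:", paste(x$sizes, collapse = "/"),
      "| SSE:", format(x$sse, digits = 6), "\n")
  invisible(x)
}

#' Cluster-distance anomaly score
#'
#' The dining anomaly score of a student is the Euclidean distance to the
#' centroid of the student's own cluster, weighted up for small clusters:
#' `M = D(point, centroid) * (1 - cluster_size / cohort_size)`. A student
#' sitting exactly on its centroid scores 0, and members of a cluster
#' containing the whole cohort score 0 regardless of distance.
#'
#' @param point numeric feature vector of the student.
#' @param centroid centroid of the student's cluster, same length.
#' @param cluster_size number of students in that cluster (>= 1).
#' @param cohort_size total number of students (>= cluster_size).
#' @return Non-negative score `M`.
#' @export
anomaly_score <- function(point, centroid, cluster_size, cohort_size) {
  if (cluster_size < 1 || cohort_size < cluster_size) {
    stop("validation error: need 1 <= cluster_size <= cohort_size", call. = FALSE)
  }
  stopifnot(length(point) == length(centroid))
  sqrt(sum((point - centroid)^2)) * (1 - cluster_size / cohort_size)
}

#' Anomaly scores for every student in a clustering
#'
#' Applies [anomaly_score()] to each row of `x` in the (standardized) space
#' the clustering was fitted in.
#'
#' @param clustering a [cluster_dining()] result.
#' @param x the feature matrix the clustering was fitted on.
#' @return Numeric vector of scores, one per row of `x`.
#' @export
anomaly_scores <- function(clustering, x) {
  x <- as.matrix(x)
  z <- sweep(sweep(x, 2, clustering$feature_center), 2, clustering$feature_scale, "/")
  n <- nrow(z)
  vapply(seq_len(n), function(i) {
    ci <- clustering$assignments[i]
    anomaly_score(z[i, ], clustering$centers[ci, ], clustering$sizes[ci], n)
  }, numeric(1))
}
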