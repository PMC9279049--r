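#' Assemble the per-student feature table
#'
#' Runs preprocessing ([clean_consumption()], [fill_missing_credits()]) and
#' every engineered feature over a cohort, producing one row per student
#' with a fixed column order:
#'
#' 1. `student_id`, `level`
#' 2. `gpa` — aggregate grade-point average ([gpa_average()])
#' 3. `dining_entropy` — Shannon entropy of the meal-window distribution
#' 4. `anomaly_m` — cluster-distance dining anomaly score
#' 5. `insomnia_p` — insomnia probability ([insomnia_probability()])
#' 6. `sessions_per_day`, `night_fraction` — aggregate internet-usage
#'    summaries (mean daily session count; fraction of sessions starting in
#'    00:00--06:00)
#' 7. `md` — binary label (1 = any concern level), `label` — severity
#'
#' Students missing an entire channel are flagged, imputed with the cohort
#' median of the feature, and reported via a warning; the returned table
#' has no missing values.
#'
#' @param cohort a `cohort` object (possibly corrupted; preprocessing is
#'   applied first).
#' @param seed seed for the dining clustering restarts.
#' @param gpa_denominator passed to [gpa_average()].
#' @param k number of dining clusters.
#' @return Data frame of features with attribute `clustering` (the fitted
#'   [cluster_dining()] object) and `imputed` (logical matrix of imputations).
#' @export
build_feature_table <- function(cohort, seed = 1L,
                                gpa_denominator = c("score", "credit"),
                                k = 3L) {
  stopifnot(inherits(cohort, "cohort"))
  gpa_denominator <- match.arg(gpa_denominator)
  students <- cohort$students
  ids <- students$student_id
  n_days <- cohort$config$n_days

  meals <- clean_consumption(cohort$meals)
  courses <- fill_missing_credits(cohort$courses)

  gpa <- stats::setNames(rep(NA_real_, length(ids)), ids)
  by_student <- split(seq_len(nrow(courses)), courses$student_id)
  for (sid in intersect(ids, names(by_student))) {
    idx <- by_student[[sid]]
    gpa[sid] <- gpa_average(courses$score[idx], courses$credit[idx],
                            denominator = gpa_denominator)
  }

  dining <- dining_feature_matrix(meals, ids, n_days)
  empty_dining <- attr(dining, "empty")
  clustering <- cluster_dining(dining, k = k, seed = seed)
  m <- anomaly_scores(clustering, dining)
  entropy <- dining[, "entropy"]
  entropy[empty_dining] <- NA_real_
  m[empty_dining] <- NA_real_

  insomnia_p <- insomnia_probability(students$insomnia_nights, n_days)

  n_sessions <- table(factor(cohort$sessions$student_id, levels = ids))
  sessions_per_day <- as.vector(n_sessions) / n_days
  night <- cohort$sessions$start < 360
  n_night <- table(factor(cohort$sessions$student_id[night], levels = ids))
  night_fraction <- ifelse(n_sessions > 0, as.vector(n_night) / as.vector(n_sessions), NA_real_)

  out <- data.frame(student_id = ids,
                    level = students$level,
                    gpa = unname(gpa),
                    dining_entropy = unname(entropy),
                    anomaly_m = unname(m),
                    insomnia_p = unname(insomnia_p),
                    sessions_per_day = sessions_per_day,
                    night_fraction = night_fraction,
                    md = students$md,
                    label = students$label,
                    stringsAsFactors = FALSE)

  feat_cols <- c("gpa", "dining_entropy", "anomaly_m", "insomnia_p",
                 "sessions_per_day", "night_fraction")
  imputed <- is.na(as.matrix(out[feat_cols]))
  if (any(imputed)) {
    warning(sum(rowSums(imputed) > 0),
            " student(s) missing a channel; features imputed with cohort medians",
            call. = FALSE)
    for (cl in feat_cols) {
      nas <- is.na(out[[cl]])
      if (any(nas)) out[[cl]][nas] <- stats::median(out[[cl]], na.rm = TRUE)
    }
  }
  attr(out, "clustering") <- clustering
  attr(out, "imputed") <- imputed
  out
}

#' Feature-column groups by data source
#'
#' Maps the three behavioral data sources (performance, consumption, network) to
#' the columns of the feature table; used by the ablation driver.
#'
#' @return Named list of character vectors.
#' @export
feature_channels <- function() {
  list(performance = "gpa",
       consumption = c("dining_entropy", "anomaly_m"),
       network = c("insomnia_p", "sessions_per_day", "night_fraction"))
}

#' Write the feature table with a JSON schema sidecar
#'
#' @param features a [build_feature_table()] result.
#' @param path output CSV path; the schema is written next to it as
#'   `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  schema <- list(columns = lapply(features, function(col) class(col)[1]),
                 feature_columns = c("gpa", "dining_entropy", "anomaly_m",
                                     "insomnia_p", "sessions_per_day",
                                     "night_fraction"),
                 label_columns = c("md", "label"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
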