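#' Cohort simulation settings
#'
#' Bundles the knobs of the synthetic boarding-school cohort generator:
#' cohort size and composition, the prevalence and severity mix of the
#' positive (mental-disorder, MD) class, the standardized effect sizes that
#' control how strongly MD status is expressed in each behavioral channel,
#' and the observation window.
#'
#' Effect sizes are interpreted on a standardized scale: an effect of 1
#' shifts the corresponding channel of a moderate-severity MD student by
#' roughly one baseline standard deviation (see the channel definitions in
#' [simulate_cohort()]). Setting every effect to 0 yields a null cohort in
#' which MD and non-MD students are statistically indistinguishable.
#'
#' @param n_students total cohort size; must equal `3 * per_level`.
#' @param per_level students per school level (primary, junior, senior).
#' @param md_prevalence probability that a student belongs to the MD class.
#' @param severity_mix length-3 probabilities (mild, moderate, severe)
#'   within the MD class; must sum to 1.
#' @param effect_sizes named numeric vector with entries
#'   `dining_irregularity`, `late_night_use`, `grade_deficit`,
#'   `insomnia_rate`; non-negative standardized effects.
#' @param n_days number of simulated days.
#' @param n_courses courses per student.
#' @param seed integer seed controlling all randomness of the generator.
#'
#' @return A `cohort_config` object (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_students = 210L,
                          per_level = 70L,
                          md_prevalence = 0.30,
                          severity_mix = c(mild = 0.5, moderate = 0.3, severe = 0.2),
                          effect_sizes = c(dining_irregularity = 1,
                                           late_night_use = 1,
                                           grade_deficit = 1,
                                           insomnia_rate = 1),
                          n_days = 60L,
                          n_courses = 8L,
                          seed = 1L) {
  n_students <- as.integer(n_students)
  per_level <- as.integer(per_level)
  if (3L * per_level != n_students) {
    stop("configuration error: per-level counts (3 x ", per_level,
         ") must sum to n_students (", n_students, ")", call. = FALSE)
  }
  if (!is.numeric(md_prevalence) || md_prevalence <= 0 || md_prevalence >= 1) {
    stop("configuration error: md_prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (length(severity_mix) != 3L || any(severity_mix < 0) ||
      abs(sum(severity_mix) - 1) > 1e-9) {
    stop("configuration error: severity_mix must be 3 non-negative fractions summing to 1",
         call. = FALSE)
  }
  names(severity_mix) <- c("mild", "moderate", "severe")
  wanted <- c("dining_irregularity", "late_night_use", "grade_deficit", "insomnia_rate")
  if (!all(wanted %in% names(effect_sizes))) {
    stop("configuration error: effect_sizes must name ",
         paste(wanted, collapse = ", "), call. = FALSE)
  }
  effect_sizes <- effect_sizes[wanted]
  if (any(effect_sizes < 0)) {
    stop("configuration error: effect sizes must be non-negative", call. = FALSE)
  }
  structure(list(n_students = n_students,
                 per_level = per_level,
                 md_prevalence = md_prevalence,
                 severity_mix = severity_mix,
                 effect_sizes = effect_sizes,
                 n_days = as.integer(n_days),
                 n_courses = as.integer(n_courses),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# severity scaling of every planted channel shift; "none" carries 0 so that
# non-MD students are untouched by the effect sizes
.severity_mult <- c(none = 0, mild = 0.6, moderate = 1, severe = 1.4)

#' Simulate a synthetic boarding-school cohort
#'
#' Generates per-student multimodal behavioral logs with a planted
#' statistical dependence between mental-disorder (MD) status and four
#' channels: irregular meal timing, late-night internet activity, lowered
#' course scores and insomnia frequency. The generative process is:
#'
#' * **Meals** — three canonical daily windows centred at 07:30, 12:00 and
#'   18:00. Each window is attended with a baseline probability of 0.92 and
#'   the event time is the centre plus Gaussian jitter (SD 25 min). For MD
#'   students the jitter SD is inflated and the attendance probability
#'   lowered in proportion to `dining_irregularity`, producing higher
#'   dispersion over the meal windows.
#' * **Internet sessions** — a Poisson(3) count per day; each session starts
#'   either in a daytime component (Gaussian around 16:30) or a night
#'   component (uniform over 00:00--06:00). The night weight rises with
#'   `late_night_use` for MD students.
#' * **Courses** — integer scores drawn from Normal(75, 8), clamped to
#'   \[50, 100\], with the mean shifted down by `8 * grade_deficit` (scaled
#'   by severity) for MD students; credits are fixed per course id.
#' * **Insomnia nights** — Binomial(`n_days`, p) with baseline p = 0.06,
#'   raised with `insomnia_rate` for MD students.
#'
#' Severity (mild/moderate/severe) scales every shift by 0.6/1/1.4. All
#' randomness flows from `config$seed`; identical configs give identical
#' cohorts.
#'
#' @param config a [cohort_config()] object.
#' @return A `cohort` object: a list with data frames `students` (id, level,
#'   gender, insomnia_nights, label, md), `meals` (student_id, day, minute),
#'   `sessions` (student_id, day, start, end), `courses` (student_id,
#'   course_id, score, credit) and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n <- config$n_students
  es <- config$effect_sizes
  ids <- sprintf("S%04d", seq_len(n))
  level <- factor(rep(c("primary", "junior", "senior"), each = config$per_level),
                  levels = c("primary", "junior", "senior"))
  # balanced gender within level
  gender <- factor(unlist(lapply(seq_len(3), function(i) {
    g <- rep(c("F", "M"), length.out = config$per_level)
    sample(g)
  })), levels = c("F", "M"))

  md <- stats::rbinom(n, 1L, config$md_prevalence)
  label <- rep("none", n)
  n_md <- sum(md)
  if (n_md > 0) {
    label[md == 1L] <- sample(c("mild", "moderate", "severe"), n_md,
                              replace = TRUE, prob = config$severity_mix)
  }
  label <- factor(label, levels = c("none", "mild", "moderate", "severe"))
  sev <- .severity_mult[as.character(label)]

  ## ---- meals -------------------------------------------------------------
  centers <- c(450, 720, 1080)            # 07:30, 12:00, 18:00 in minutes
  n_days <- config$n_days
  occ_student <- rep(seq_len(n), each = n_days * 3L)
  occ_day <- rep(rep(seq_len(n_days), each = 3L), times = n)
  occ_center <- rep(centers, times = n * n_days)
  occ_sev <- sev[occ_student]
  p_attend <- pmax(0.4, 0.92 - 0.10 * es[["dining_irregularity"]] * occ_sev)
  jitter_sd <- 25 * (1 + 0.8 * es[["dining_irregularity"]] * occ_sev)
  attend <- stats::rbinom(length(occ_student), 1L, p_attend) == 1L
  minute <- round(occ_center + stats::rnorm(length(occ_student), 0, jitter_sd))
  minute <- pmin(pmax(minute, 0), 1439)
  meals <- data.frame(student_id = ids[occ_student[attend]],
                      day = occ_day[attend],
                      minute = minute[attend],
                      stringsAsFactors = FALSE)
  meals <- meals[!duplicated(meals[c("student_id", "day", "minute")]), ]
  meals <- meals[order(meals$student_id, meals$day, meals$minute), ]
  rownames(meals) <- NULL

  ## ---- internet sessions -------------------------------------------------
  sd_counts <- stats::rpois(n * n_days, 3)
  ses_student <- rep(rep(seq_len(n), each = n_days), times = 1)[rep(seq_len(n * n_days), sd_counts)]
  ses_day <- rep(rep(seq_len(n_days), times = n), times = 1)[rep(seq_len(n * n_days), sd_counts)]
  m <- length(ses_student)
  ses_sev <- sev[ses_student]
  w_night <- pmin(0.9, 0.06 + 0.22 * es[["late_night_use"]] * ses_sev)
  is_night <- stats::rbinom(m, 1L, w_night) == 1L
  start <- numeric(m)
  start[is_night] <- stats::runif(sum(is_night), 0, 360)
  start[!is_night] <- stats::rnorm(sum(!is_night), 990, 150)
  start <- round(pmin(pmax(start, 0), 1380))
  dur <- pmin(pmax(round(stats::rexp(m, 1 / 40)) + 5, 5), 180)
  end <- pmin(start + dur, 1439)
  sessions <- data.frame(student_id = ids[ses_student], day = ses_day,
                         start = start, end = end, stringsAsFactors = FALSE)
  sessions <- sessions[order(sessions$student_id, sessions$day, sessions$start), ]
  rownames(sessions) <- NULL

  ## ---- courses -----------------------------------------------------------
  n_courses <- config$n_courses
  course_ids <- sprintf("C%02d", seq_len(n_courses))
  course_credits <- rep(c(4, 3, 3, 2, 2, 1, 5, 4), length.out = n_courses)
  crs_student <- rep(seq_len(n), each = n_courses)
  crs_course <- rep(seq_len(n_courses), times = n)
  mu <- 75 - 8 * es[["grade_deficit"]] * sev[crs_student]
  score <- round(stats::rnorm(n * n_courses, mu, 8))
  score <- pmin(pmax(score, 50), 100)
  courses <- data.frame(student_id = ids[crs_student],
                        course_id = course_ids[crs_course],
                        score = score,
                        credit = course_credits[crs_course],
                        stringsAsFactors = FALSE)

  ## ---- insomnia ----------------------------------------------------------
  p_ins <- pmin(0.9, 0.06 + 0.10 * es[["insomnia_rate"]] * sev)
  insomnia_nights <- stats::rbinom(n, n_days, p_ins)

  students <- data.frame(student_id = ids, level = level, gender = gender,
                         insomnia_nights = insomnia_nights,
                         label = label, md = md, stringsAsFactors = FALSE)
  structure(list(students = students, meals = meals, sessions = sessions,
                 courses = courses, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic student cohort\n")
  cat("  students:", nrow(x$students), "(",
      sum(x$students$md), "MD /", sum(!x$students$md), "non-MD )\n")
  cat("  days:", x$config$n_days,
      "| meal events:", nrow(x$meals),
      "| net sessions:", nrow(x$sessions),
      "| course rows:", nrow(x$courses), "\n")
  invisible(x)
}

#' Inject preprocessing defects into a cohort
#'
#' Corrupts a clean cohort so the preprocessing steps can be tested against
#' known ground truth: duplicates or out-of-range minutes are injected into
#' the meal log at `noise_rate` (relative to the number of meal events), and
#' course credits are blanked at `missing_credit_rate`. The injected defects
#' are recorded in attributes `noise_ledger` (the injected meal rows, with
#' their kind) and `credit_ledger` (row indices of `courses` whose credit was
#' blanked).
#'
#' @param cohort a `cohort` object.
#' @param noise_rate fraction of meal rows to inject as noise (half exact
#'   duplicates of existing rows, half physically impossible minutes).
#' @param missing_credit_rate fraction of course rows whose credit is set to
#'   `NA`; exactly `round(rate * nrow(courses))` rows are blanked.
#' @param seed integer seed.
#' @return The corrupted `cohort` with ground-truth ledgers attached.
#' @export
corrupt_for_preprocessing <- function(cohort, noise_rate = 0.05,
                                      missing_credit_rate = 0.05, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (noise_rate < 0 || noise_rate > 1 || missing_credit_rate < 0 || missing_credit_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_noise <- round(noise_rate * nrow(cohort$meals))
  noise_ledger <- NULL
  if (n_noise > 0) {
    n_dup <- floor(n_noise / 2)
    n_oob <- n_noise - n_dup
    dup <- cohort$meals[sample.int(nrow(cohort$meals), n_dup, replace = FALSE), , drop = FALSE]
    oob_students <- sample(cohort$students$student_id, n_oob, replace = TRUE)
    oob <- data.frame(student_id = oob_students,
                      day = sample.int(cohort$config$n_days, n_oob, replace = TRUE),
                      minute = 1440L + sample.int(500L, n_oob, replace = TRUE),
                      stringsAsFactors = FALSE)
    noise_ledger <- rbind(cbind(dup, kind = "duplicate"),
                          cbind(oob, kind = "out_of_range"))
    meals <- rbind(cohort$meals, noise_ledger[names(cohort$meals)])
    meals <- meals[order(meals$student_id, meals$day, meals$minute), ]
    rownames(meals) <- NULL
    cohort$meals <- meals
  }
  n_blank <- round(missing_credit_rate * nrow(cohort$courses))
  credit_ledger <- integer(0)
  if (n_blank > 0) {
    credit_ledger <- sort(sample.int(nrow(cohort$courses), n_blank, replace = FALSE))
    cohort$courses$credit[credit_ledger] <- NA_real_
  }
  attr(cohort, "noise_ledger") <- noise_ledger
  attr(cohort, "credit_ledger") <- credit_ledger
  cohort
}

#' Write / read a cohort as a CSV bundle
#'
#' Serializes the four channels to `students.csv`, `meals.csv`,
#' `sessions.csv` and `courses.csv` plus a `manifest.json` holding the
#' generator configuration. Column names are stable and documented in
#' [simulate_cohort()].
#'
#' @param cohort a `cohort` object.
#' @param dir output directory, created if needed.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns the
#'   reconstructed `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$students, file.path(dir, "students.csv"), row.names = FALSE)
  utils::write.csv(cohort$meals, file.path(dir, "meals.csv"), row.names = FALSE)
  utils::write.csv(cohort$sessions, file.path(dir, "sessions.csv"), row.names = FALSE)
  utils::write.csv(cohort$courses, file.path(dir, "courses.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$severity_mix <- as.list(cfg$severity_mix)
  cfg$effect_sizes <- as.list(cfg$effect_sizes)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  config <- cohort_config(n_students = man$n_students, per_level = man$per_level,
                          md_prevalence = man$md_prevalence,
                          severity_mix = unlist(man$severity_mix),
                          effect_sizes = unlist(man$effect_sizes),
                          n_days = man$n_days, n_courses = man$n_courses,
                          seed = man$seed)
  students <- utils::read.csv(file.path(dir, "students.csv"), stringsAsFactors = FALSE)
  students$level <- factor(students$level, levels = c("primary", "junior", "senior"))
  students$gender <- factor(students$gender, levels = c("F", "M"))
  students$label <- factor(students$label, levels = c("none", "mild", "moderate", "severe"))
  structure(list(students = students,
                 meals = utils::read.csv(file.path(dir, "meals.csv"), stringsAsFactors = FALSE),
                 sessions = utils::read.csv(file.path(dir, "sessions.csv"), stringsAsFactors = FALSE),
                 courses = utils::read.csv(file.path(dir, "courses.csv"), stringsAsFactors = FALSE),
                 config = config),
            class = "cohort")
}
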