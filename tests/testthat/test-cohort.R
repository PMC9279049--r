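test_that("default configuration yields 210 students, 70 per level, balanced gender", {
  co <- simulate_cohort(cohort_config(seed = 1))
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co$students), 210L)
  expect_equal(as.vector(table(co$students$level)), c(70L, 70L, 70L))
  gl <- table(co$students$level, co$students$gender)
  expect_true(all(gl == 35L))
})

test_that("simulation is deterministic and serialization round-trips", {
  cfg <- cohort_config(n_students = 30, per_level = 10, n_days = 14, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in c("students.csv", "meals.csv", "sessions.csv", "courses.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  rt <- read_cohort(d1)
  expect_equal(rt$students, a$students)
  expect_equal(rt$meals, a$meals)
  expect_equal(rt$config$effect_sizes, a$config$effect_sizes)
})

test_that("records respect the structural invariants", {
  co <- small_cohort(seed = 3)
  expect_true(all(co$sessions$start < co$sessions$end))
  expect_true(all(co$sessions$start >= 0 & co$sessions$end < 1440))
  expect_true(all(co$meals$minute >= 0 & co$meals$minute < 1440))
  expect_false(any(duplicated(co$meals[c("student_id", "day", "minute")])))
  expect_true(all(co$students$insomnia_nights <= co$config$n_days))
  expect_true(all(co$courses$score >= 50 & co$courses$score <= 100))
  # ordering by (student, day, time)
  expect_false(is.unsorted(order(co$meals$student_id, co$meals$day, co$meals$minute)))
  # label none <=> non-MD process
  expect_identical(co$students$md == 0L, co$students$label == "none")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_students = 200, per_level = 70), "configuration")
  expect_error(cohort_config(md_prevalence = 0), "configuration")
  expect_error(cohort_config(severity_mix = c(0.5, 0.4, 0.2)), "configuration")
  expect_error(cohort_config(effect_sizes = c(dining_irregularity = -1,
                                              late_night_use = 1,
                                              grade_deficit = 1,
                                              insomnia_rate = 1)),
               "non-negative")
})

test_that("zero effect sizes leave MD and non-MD channels indistinguishable", {
  co <- simulate_cohort(cohort_config(
    n_students = 2001, per_level = 667, md_prevalence = 0.4,
    effect_sizes = c(dining_irregularity = 0, late_night_use = 0,
                     grade_deficit = 0, insomnia_rate = 0),
    n_days = 14, seed = 21))
  md <- co$students$md == 1
  # per-channel two-sample tests at alpha = 0.01
  score_by <- tapply(co$courses$score, co$courses$student_id, mean)[co$students$student_id]
  expect_gt(stats::t.test(score_by[md], score_by[!md])$p.value, 0.01)
  expect_gt(stats::t.test(co$students$insomnia_nights[md],
                          co$students$insomnia_nights[!md])$p.value, 0.01)
  night <- co$sessions$start < 360
  nf <- tapply(night, co$sessions$student_id, mean)[co$students$student_id]
  expect_gt(stats::t.test(nf[md], nf[!md])$p.value, 0.01)
})

test_that("planted gaps grow with each single effect size", {
  gap <- function(es_name, es) {
    effects <- c(dining_irregularity = 0, late_night_use = 0,
                 grade_deficit = 0, insomnia_rate = 0)
    effects[es_name] <- es
    vals <- sapply(1:4, function(s) {
      co <- simulate_cohort(cohort_config(n_students = 999, per_level = 333,
                                          effect_sizes = effects,
                                          n_days = 14, seed = s))
      md <- co$students$md == 1
      switch(es_name,
        insomnia_rate = mean(co$students$insomnia_nights[md]) -
          mean(co$students$insomnia_nights[!md]),
        grade_deficit = {
          sb <- tapply(co$courses$score, co$courses$student_id, mean)[co$students$student_id]
          mean(sb[!md]) - mean(sb[md])
        },
        late_night_use = {
          night <- co$sessions$start < 360
          nf <- tapply(night, co$sessions$student_id, mean)[co$students$student_id]
          mean(nf[md], na.rm = TRUE) - mean(nf[!md], na.rm = TRUE)
        },
        dining_irregularity = {
          mw <- clean_consumption(co$meals)
          dm <- dining_feature_matrix(mw, co$students$student_id, 14)
          mean(dm[md, "entropy"]) - mean(dm[!md, "entropy"])
        })
    })
    mean(vals)
  }
  for (ch in c("dining_irregularity", "late_night_use", "grade_deficit",
               "insomnia_rate")) {
    g0 <- gap(ch, 0.5)
    g1 <- gap(ch, 1.5)
    expect_gt(g1, g0)
  }
})

test_that("label marginals match prevalence and severity mix", {
  co <- simulate_cohort(cohort_config(n_students = 2001, per_level = 667,
                                      md_prevalence = 0.3, n_days = 7, seed = 5))
  n <- nrow(co$students)
  n_md <- sum(co$students$md)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.3)
  expect_gte(n_md, ci[1]); expect_lte(n_md, ci[2])
  sev <- table(co$students$label[co$students$md == 1])
  mix <- c(mild = 0.5, moderate = 0.3, severe = 0.2)
  for (lv in names(mix)) {
    ci <- stats::qbinom(c(0.005, 0.995), n_md, mix[[lv]])
    expect_gte(sev[[lv]], ci[1]); expect_lte(sev[[lv]], ci[2])
  }
})

test_that("corruption injects exactly the requested defects and records them", {
  co <- small_cohort(seed = 7)
  expect_identical(corrupt_for_preprocessing(co, 0, 0, seed = 1)$meals, co$meals)
  cc <- corrupt_for_preprocessing(co, noise_rate = 0.05,
                                  missing_credit_rate = 0.1, seed = 2)
  n_noise <- round(0.05 * nrow(co$meals))
  expect_equal(nrow(cc$meals), nrow(co$meals) + n_noise)
  expect_equal(nrow(attr(cc, "noise_ledger")), n_noise)
  expect_equal(length(attr(cc, "credit_ledger")),
               round(0.1 * nrow(co$courses)))
  expect_equal(sum(is.na(cc$courses$credit)), round(0.1 * nrow(co$courses)))
})
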