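#' Remove noise events from the consumption log
#'
#' Drops physically impossible meal events (minute outside \[0, 1440), or
#' non-finite fields) and exact duplicates of the (student, day, minute)
#' key, then re-sorts by that key. Clean input passes through unchanged.
#'
#' @param meals data frame with columns `student_id`, `day`, `minute`.
#' @return The cleaned, sorted meal log.
#' @export
clean_consumption <- function(meals) {
  stopifnot(all(c("student_id", "day", "minute") %in% names(meals)))
  ok <- is.finite(meals$minute) & meals$minute >= 0 & meals$minute < 1440 &
    is.finite(meals$day) & meals$day >= 1
  meals <- meals[ok, , drop = FALSE]
  meals <- meals[!duplicated(meals[c("student_id", "day", "minute")]), , drop = FALSE]
  meals <- meals[order(meals$student_id, meals$day, meals$minute), , drop = FALSE]
  rownames(meals) <- NULL
  meals
}

#' Impute missing course credits
#'
#' Replaces each missing credit by the cohort-wide median of the observed
#' credits for the same course id. Fails if some course id has no observed
#' credit anywhere, or if an imputed/observed credit is not positive.
#'
#' @param courses data frame with columns `student_id`, `course_id`,
#'   `score`, `credit` (credit may contain `NA`).
#' @return `courses` with all credits filled in.
#' @export
fill_missing_credits <- function(courses) {
  stopifnot(all(c("course_id", "credit") %in% names(courses)))
  miss <- is.na(courses$credit)
  if (!any(miss)) return(courses)
  med <- tapply(courses$credit[!miss], courses$course_id[!miss], stats::median)
  need <- unique(courses$course_id[miss])
  absent <- setdiff(need, names(med))
  if (length(absent) > 0) {
    stop("imputation error: no observed credit for course(s) ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  courses$credit[miss] <- unname(med[courses$course_id[miss]])
  if (any(courses$credit <= 0)) {
    stop("imputation error: non-positive credit after filling", call. = FALSE)
  }
  courses
}
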