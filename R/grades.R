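#' Grade-point transform of a course score
#'
#' Maps a raw 0--100 course score to a grade point via the affine rule
#' `(score - 50) / 10`, so a pass mark of 50 maps to 0 and a perfect score
#' to 5.
#'
#' @param score numeric score(s) in \[0, 100\].
#' @return The grade point(s).
#' @export
grade_point <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 100)) {
    stop("validation error: scores must lie in [0, 100]", call. = FALSE)
  }
  (score - 50) / 10
}

#' Credit-weighted course quality
#'
#' The per-course quality is the product of the course credit and its grade
#' point.
#'
#' @param credit non-negative course credit(s).
#' @param gpa grade point(s), typically from [grade_point()].
#' @return `credit * gpa`.
#' @export
course_quality <- function(credit, gpa) {
  if (any(!is.finite(credit)) || any(credit < 0)) {
    stop("validation error: credits must be non-negative", call. = FALSE)
  }
  credit * gpa
}

#' Aggregate grade-point average
#'
#' Aggregates per-course qualities `Q_i = credit_i * grade_point(score_i)`
#' into a single average. The default denominator is the sum of raw scores,
#' `sum(Q_i) / sum(score_i)`; the conventional credit-weighted form
#' `sum(Q_i) / sum(credit_i)` is available via `denominator = "credit"`.
#'
#' @param score numeric vector of course scores in \[0, 100\].
#' @param credit numeric vector of non-negative credits, same length.
#' @param denominator `"score"` (default) or `"credit"`.
#' @return The scalar average.
#' @export
gpa_average <- function(score, credit, denominator = c("score", "credit")) {
  denominator <- match.arg(denominator)
  stopifnot(length(score) == length(credit))
  q <- course_quality(credit, grade_point(score))
  den <- if (denominator == "score") sum(score) else sum(credit)
  if (den <= 0) {
    stop("undefined-average error: denominator sum is not positive", call. = FALSE)
  }
  sum(q) / den
}
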