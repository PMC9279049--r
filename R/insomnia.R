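#' Insomnia probability
#'
#' The fraction of observed nights a student was flagged as insomniac:
#' `P = insomnia_nights / n_days`.
#'
#' @param insomnia_nights count of insomnia nights, in \[0, `n_days`\].
#' @param n_days number of observed days (> 0).
#' @return Probability in \[0, 1\]; vectorized over `insomnia_nights`.
#' @export
insomnia_probability <- function(insomnia_nights, n_days) {
  if (any(n_days <= 0)) {
    stop("validation error: n_days must be positive", call. = FALSE)
  }
  if (any(insomnia_nights < 0) || any(insomnia_nights > n_days)) {
    stop("validation error: insomnia_nights must lie in [0, n_days]", call. = FALSE)
  }
  insomnia_nights / n_days
}

#' Behavioral insomnia nights from session logs
#'
#' For logs without an explicit insomnia indicator, a night is flagged when
#' the student has any internet session intersecting 00:00--06:00 of that
#' day. Returns the per-student count of such nights.
#'
#' @param sessions session log (`student_id`, `day`, `start`, `end`).
#' @param student_ids roster fixing output order.
#' @return Named integer vector of night counts.
#' @export
insomnia_nights_from_sessions <- function(sessions, student_ids) {
  night <- sessions[sessions$start < 360, c("student_id", "day")]
  night <- unique(night)
  counts <- table(factor(night$student_id, levels = student_ids))
  stats::setNames(as.integer(counts), student_ids)
}
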