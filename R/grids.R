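#' Internet-activity grids
#'
#' Encodes each student's session log as a stack of weekly day-by-hour
#' matrices: entry (d, h) is the number of minutes online during hour `h`
#' of weekday `d`, normalized by 60 to lie in \[0, 1\] (capped at 1 when
#' overlapping sessions exceed the hour). Days are grouped into weeks of
#' `week_length`; a trailing partial week is zero-padded. This grid is the
#' input representation for the convolutional trajectory models.
#'
#' @param cohort a `cohort` object.
#' @param week_length days per week-window (default 7).
#' @return Numeric array of dim `(n_students, n_weeks, week_length, 24)`
#'   with `dimnames` on the student axis.
#' @export
activity_grids <- function(cohort, week_length = 7L) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- cohort$students$student_id
  n <- length(ids)
  n_days <- cohort$config$n_days
  n_weeks <- ceiling(n_days / week_length)
  out <- array(0, dim = c(n, n_weeks, week_length, 24L),
               dimnames = list(ids, NULL, NULL, NULL))
  ses <- cohort$sessions
  if (nrow(ses) == 0) return(out)
  fh <- floor(ses$start / 60)
  lh <- floor((ses$end - 1e-9) / 60)
  span <- lh - fh + 1L
  ridx <- rep(seq_len(nrow(ses)), span)
  hour <- sequence(span, from = fh)
  overlap <- pmin(ses$end[ridx], 60 * (hour + 1)) - pmax(ses$start[ridx], 60 * hour)
  sid <- match(ses$student_id[ridx], ids)
  day <- ses$day[ridx]
  week <- (day - 1L) %/% week_length + 1L
  dow <- (day - 1L) %% week_length + 1L
  # flat index into the 4-d array (student fastest, then week, dow, hour)
  flat <- sid + n * ((week - 1L) + n_weeks * ((dow - 1L) + week_length * hour))
  acc <- rowsum(overlap, group = flat)
  out[as.integer(rownames(acc))] <- out[as.integer(rownames(acc))] + acc[, 1]
  pmin(out / 60, 1)
}

#' Serialize activity grids as a dense array file with a shape manifest
#'
#' Values are written flattened in column-major order to a plain-text file,
#' one value per line, with a JSON sidecar recording the dimensions and
#' student ids; `read_grids` reverses the process.
#'
#' @param grids array from [activity_grids()].
#' @param path output file; the manifest is written to `<path>.shape.json`.
#' @return `path` (write) or the restored array (read).
#' @export
write_grids <- function(grids, path) {
  writeLines(format(as.vector(grids), trim = TRUE, digits = 15), path)
  jsonlite::write_json(list(dim = dim(grids),
                            student_ids = dimnames(grids)[[1]]),
                       paste0(path, ".shape.json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_grids
#' @export
read_grids <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".shape.json"), simplifyVector = TRUE)
  arr <- array(as.numeric(readLines(path)), dim = man$dim)
  dimnames(arr) <- list(man$student_ids, NULL, NULL, NULL)
  arr
}
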