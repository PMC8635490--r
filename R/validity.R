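#' Spontaneous-phase snippet validity
#'
#' Snippets whose face was occluded, out of frame, or missed by the AU
#' detector are invalid. In addition, when more than half of the snippets of
#' a participant x embodiment block are missing, the remaining snippets of
#' that block are excluded as well (the block is judged unreliable as a
#' whole). "Half" is evaluated against the nominal block size by default.
#'
#' @param records Data frame with at least `participant_id`, `embodiment`
#'   and `missing` (logical: occluded/undetected) columns; one row per
#'   snippet.
#' @param nominal_n Nominal snippets per participant x embodiment block
#'   (default 12). Set `NULL` to evaluate against the observed block size.
#' @return `records` with a logical `valid` column (re)computed.
#' @export
#' @examples
#' rec <- data.frame(participant_id = "P1", embodiment = "virtual",
#'                   missing = rep(c(TRUE, FALSE), c(7, 5)))
#' sum(filter_spontaneous_validity(rec)$valid)  # 0: 7 of 12 missing
filter_spontaneous_validity <- function(records, nominal_n = 12L) {
  key <- interaction(records$participant_id, records$embodiment, drop = TRUE)
  valid <- !records$missing
  for (k in levels(key)) {
    idx <- which(key == k)
    denom <- if (is.null(nominal_n)) length(idx) else nominal_n
    if (sum(records$missing[idx]) > denom / 2) valid[idx] <- FALSE
  }
  records$valid <- valid
  records
}

#' Instructed-phase snippet validity
#'
#' Occluded/undetected (or too-short) snippets are invalid; additionally, a
#' participant x embodiment block that retains 5 or fewer valid snippets is
#' excluded entirely.
#'
#' @param records Data frame with `participant_id`, `embodiment`, `missing`.
#' @param min_valid Blocks with at most this many valid snippets are dropped
#'   (default 5).
#' @return `records` with a logical `valid` column (re)computed.
#' @export
filter_instructed_validity <- function(records, min_valid = 5L) {
  key <- interaction(records$participant_id, records$embodiment, drop = TRUE)
  valid <- !records$missing
  for (k in levels(key)) {
    idx <- which(key == k)
    if (sum(valid[idx]) <= min_valid) valid[idx] <- FALSE
  }
  records$valid <- valid
  records
}

#' Exclusion accounting per phase
#'
#' @param records Data frame with `valid` column.
#' @return List with counts and the excluded fraction.
#' @export
exclusion_summary <- function(records) {
  n <- nrow(records)
  n_valid <- sum(records$valid)
  list(n_snippets = n, n_valid = n_valid, n_excluded = n - n_valid,
       excluded_fraction = if (n) (n - n_valid) / n else NA_real_)
}
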