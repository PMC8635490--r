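#' CRQA configuration
#'
#' Parameters of the cross-recurrence quantification of instructed mimicry.
#' Two frames — one of the participant, one of the agent — recur when the
#' distance between their AU intensity vectors is below the threshold
#' `eps` on the ordinal 0-5 scale (Manhattan norm by default; "a match only
#' when the distance is less than two" is the strict convention). Diagonal
#' lines of recurrent points mark stretches where the two expression
#' trajectories run in parallel; lines shorter than `l_min` samples
#' (default 8, about 250 ms at 30 fps) are treated as noise by the
#' line-based measures.
#'
#' Determinism comes in two variants. `normalized` divides the recurrent
#' points on long diagonals by *all* recurrent points
#' (sum of l times P(l) over all l), so DET is a fraction in [0, 1];
#' `as_printed` divides by the number of diagonal *lines*
#' (sum of P(l) over all l), which can exceed 1. Both are computed; `det_variant`
#' selects which one populates the headline `det` field.
#'
#' @param eps Recurrence threshold (>= 0) on the intensity scale.
#' @param norm Distance over AU channels: "manhattan" (default) or
#'   "euclidean".
#' @param l_min Minimal diagonal line length in samples.
#' @param det_variant "normalized" (default) or "as_printed".
#' @param theta_convention "strict" (distance < eps, default) or
#'   "inclusive" (distance <= eps, the Heaviside-at-zero convention of most
#'   CRQA software).
#' @param channel_policy Which AU channels form the feature vector:
#'   "emotion_pattern" (default; the union of the stimulus emotion's
#'   [emotion_patterns()] AU sets, 1-4 channels) or "all" (all nine).
#' @return A `crqa_config` list.
#' @export
crqa_config <- function(eps = 2, norm = c("manhattan", "euclidean"),
                        l_min = 8L,
                        det_variant = c("normalized", "as_printed"),
                        theta_convention = c("strict", "inclusive"),
                        channel_policy = c("emotion_pattern", "all")) {
  stopifnot(eps >= 0, l_min >= 1L)
  structure(list(eps = eps, norm = match.arg(norm),
                 l_min = as.integer(l_min),
                 det_variant = match.arg(det_variant),
                 theta_convention = match.arg(theta_convention),
                 channel_policy = match.arg(channel_policy)),
            class = "crqa_config")
}

#' Cross-recurrence matrix of two AU series
#'
#' Entry (i, j) is 1 when frame i of `f1` and frame j of `f2` are within
#' `eps` of each other in AU feature space (strictly below `eps` under the
#' default convention).
#'
#' @param f1,f2 [au_series()] objects (or plain matrices) sharing the same
#'   channel set; `f1` spans the rows (N frames), `f2` the columns (M).
#' @param config A [crqa_config()].
#' @return Integer 0/1 matrix of dimension N x M.
#' @export
#' @examples
#' a <- au_series(matrix(2L, 10, 9), fps = 30)
#' all(cross_recurrence_matrix(a, a) == 1L)
cross_recurrence_matrix <- function(f1, f2, config = crqa_config()) {
  m1 <- unclass(f1); m2 <- unclass(f2)
  if (is.null(dim(m1))) m1 <- matrix(m1, ncol = 1L)
  if (is.null(dim(m2))) m2 <- matrix(m2, ncol = 1L)
  if (ncol(m1) != ncol(m2) ||
      (!is.null(colnames(m1)) && !is.null(colnames(m2)) &&
       !identical(colnames(m1), colnames(m2)))) {
    stop("f1 and f2 must share the same channel set, in the same order")
  }
  d <- matrix(0, nrow(m1), nrow(m2))
  for (k in seq_len(ncol(m1))) {
    dk <- outer(m1[, k], m2[, k], "-")
    d <- d + (if (config$norm == "manhattan") abs(dk) else dk^2)
  }
  if (config$norm == "euclidean") d <- sqrt(d)
  crp <- if (config$theta_convention == "strict") d < config$eps
         else d <= config$eps
  storage.mode(crp) <- "integer"
  crp
}

#' Histogram of diagonal line lengths in a cross-recurrence plot
#'
#' Scans every diagonal of the CRP (offsets -(N-1) .. M-1) and counts each
#' maximal run of consecutive recurrent points by its exact length. Isolated
#' points are lines of length 1; runs touching the matrix border count at
#' their visible length. No Theiler window is applied: the two series come
#' from distinct systems, so the main diagonal carries lag-0 signal.
#'
#' @param crp 0/1 matrix from [cross_recurrence_matrix()].
#' @return Named integer vector `P`; `P[[as.character(l)]]` is the number of
#'   maximal diagonal runs of exactly length `l`. Empty (length 0) when the
#'   CRP has no recurrent point.
#' @export
diagonal_histogram <- function(crp) {
  n <- nrow(crp); m <- ncol(crp)
  lengths <- integer(0)
  for (k in -(n - 1L):(m - 1L)) {
    i <- seq(max(1L, 1L - k), min(n, m - k))
    diagvals <- crp[cbind(i, i + k)]
    r <- rle(diagvals == 1L)
    lengths <- c(lengths, r$lengths[r$values])
  }
  if (!length(lengths)) return(stats::setNames(integer(0), character(0)))
  tab <- table(lengths)
  stats::setNames(as.integer(tab), names(tab))
}

#' Line-based CRQA measures of a cross-recurrence plot
#'
#' Computes the cross-recurrence rate `crr` (percentage of recurrent matrix
#' entries, 100 * sum(CRP) / (N * M)), the mean diagonal line length `l_mean`
#' over lines of at least `l_min` samples, the longest diagonal `l_max`, and
#' determinism `det` in both variants (see [crqa_config()]). An empty
#' recurrence set yields all-zero measures with `empty = TRUE`; when no line
#' reaches `l_min`, `l_mean` and `det` are 0 with `lines_ge_lmin = 0`.
#'
#' @param crp 0/1 matrix from [cross_recurrence_matrix()].
#' @param config A [crqa_config()].
#' @param histogram Optional precomputed [diagonal_histogram()].
#' @return A `crqa_result` list: `crr` (percent), `l_mean`, `l_max`
#'   (samples), `det` (selected variant), `det_normalized`, `det_as_printed`,
#'   `histogram`, `n`, `m`, `recurrent_points`, `lines_ge_lmin`, `empty`.
#' @export
crqa_measures <- function(crp, config = crqa_config(),
                          histogram = diagonal_histogram(crp)) {
  n <- nrow(crp); m <- ncol(crp)
  total <- sum(crp)
  if (total == 0L) {
    return(structure(list(crr = 0, l_mean = 0, l_max = 0, det = 0,
                          det_normalized = 0, det_as_printed = 0,
                          histogram = histogram, n = n, m = m,
                          recurrent_points = 0L, lines_ge_lmin = 0L,
                          empty = TRUE),
                     class = "crqa_result"))
  }
  l <- as.integer(names(histogram))
  p <- as.numeric(histogram)
  long <- l >= config$l_min
  pts_long <- sum(l[long] * p[long])
  lines_long <- sum(p[long])
  l_mean <- if (lines_long > 0) pts_long / lines_long else 0
  det_norm <- pts_long / sum(l * p)
  det_printed <- pts_long / sum(p)
  structure(list(
    crr = 100 * total / (n * m),
    l_mean = l_mean,
    l_max = max(l),
    det = if (config$det_variant == "normalized") det_norm else det_printed,
    det_normalized = det_norm,
    det_as_printed = det_printed,
    histogram = histogram, n = n, m = m,
    recurrent_points = as.integer(total),
    lines_ge_lmin = as.integer(lines_long),
    empty = FALSE
  ), class = "crqa_result")
}

#' @export
print.crqa_result <- function(x, ...) {
  cat(sprintf(
    "<crqa_result> %dx%d  cRR=%.2f%%  L=%.2f  Lmax=%d  DET=%.3f%s\n",
    x$n, x$m, x$crr, x$l_mean, as.integer(x$l_max), x$det,
    if (x$empty) "  [empty]" else ""))
  invisible(x)
}

#' One-call CRQA of a participant/agent series pair
#'
#' Restricts both series to the configured channel set, builds the CRP and
#' returns its measures.
#'
#' @param f1,f2 [au_series()] objects (participant, agent).
#' @param config A [crqa_config()].
#' @param emotion Stimulus emotion, needed when
#'   `config$channel_policy == "emotion_pattern"`; defaults to the series'
#'   emotion attribute.
#' @return A `crqa_result`.
#' @export
crqa <- function(f1, f2, config = crqa_config(),
                 emotion = attr(f2, "emotion") %||% attr(f1, "emotion")) {
  if (config$channel_policy == "emotion_pattern") {
    if (is.null(emotion)) {
      stop("channel_policy 'emotion_pattern' needs the stimulus emotion")
    }
    chans <- unique(unlist(emotion_patterns()[[emotion]]))
    f1 <- unclass(f1)[, chans, drop = FALSE]
    f2 <- unclass(f2)[, chans, drop = FALSE]
  }
  crqa_measures(cross_recurrence_matrix(f1, f2, config), config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-snippet CRQA results per participant and embodiment
#'
#' Arithmetic means of cRR, L, Lmax and DET across the valid instructed
#' snippets of each participant x embodiment block; blocks with no valid
#' snippet are absent.
#'
#' @param results Data frame with one row per valid snippet: columns
#'   `participant_id`, `group`, `embodiment`, `crr`, `l_mean`, `l_max`,
#'   `det`.
#' @return Data frame with columns `participant_id`, `group`, `embodiment`,
#'   `avg_crr`, `avg_l`, `avg_lmax`, `avg_det`, `n_valid`.
#' @export
aggregate_instructed <- function(results) {
  if (!nrow(results)) {
    return(data.frame(participant_id = character(), group = character(),
                      embodiment = character(), avg_crr = numeric(),
                      avg_l = numeric(), avg_lmax = numeric(),
                      avg_det = numeric(), n_valid = integer()))
  }
  agg <- stats::aggregate(
    results[c("crr", "l_mean", "l_max", "det")],
    by = results[c("participant_id", "group", "embodiment")],
    FUN = mean
  )
  cnt <- stats::aggregate(
    list(n_valid = results$crr),
    by = results[c("participant_id", "group", "embodiment")],
    FUN = length
  )
  out <- merge(agg, cnt,
               by = c("participant_id", "group", "embodiment"))
  names(out)[match(c("crr", "l_mean", "l_max", "det"), names(out))] <-
    c("avg_crr", "avg_l", "avg_lmax", "avg_det")
  out$n_valid <- as.integer(out$n_valid)
  out[order(out$participant_id, out$embodiment), , drop = FALSE]
}
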