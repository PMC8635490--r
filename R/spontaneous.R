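#' Mimicry analysis windows
#'
#' Spontaneous responses are scored in two post-onset intervals: Rapid Facial
#' Reactions (RFR), 0-1000 ms, capturing subperceptual muscle responses, and
#' Controlled Facial Reactions (CFR), 1000-5000 ms, capturing slower, more
#' deliberate responses. An activation counts only when the target AU pattern
#' stays active for at least `min_run` consecutive frames (3 frames = 100 ms
#' at 30 fps, the shortest time a facial muscle takes to move). Each window
#' is evaluated independently: a run straddling the boundary counts for a
#' window only if at least `min_run` of its frames fall inside that window.
#'
#' @param rfr_ms,cfr_ms Two-element numeric vectors, window bounds in ms
#'   post onset. RFR is half-open `[lo, hi)`; CFR is closed on its upper
#'   bound end-of-stimulus.
#' @param min_run Minimum consecutive active frames.
#' @return A `mimicry_windows` list.
#' @export
mimicry_windows <- function(rfr_ms = c(0, 1000), cfr_ms = c(1000, 5000),
                            min_run = 3L) {
  stopifnot(length(rfr_ms) == 2L, length(cfr_ms) == 2L,
            rfr_ms[1] < rfr_ms[2], cfr_ms[1] < cfr_ms[2],
            rfr_ms[2] <= cfr_ms[1], min_run >= 1L)
  structure(list(rfr_ms = rfr_ms, cfr_ms = cfr_ms,
                 min_run = as.integer(min_run)),
            class = "mimicry_windows")
}

# 1-based frame indices whose onset time (frame0/fps) lies in the window
window_frames <- function(bounds_ms, n, fps, closed_upper = FALSE) {
  t_ms <- (seq_len(n) - 1L) / fps * 1000
  inside <- t_ms >= bounds_ms[1] &
    (if (closed_upper) t_ms <= bounds_ms[2] else t_ms < bounds_ms[2])
  which(inside)
}

#' Binarize AU activation
#'
#' Spontaneous mimicry is expected to be low-intensity, so detection ignores
#' intensity: a channel is "active" at a frame when its intensity reaches the
#' threshold (default 1, the "trace" category).
#'
#' @param series An [au_series()] (raw ordinal or smoothed real-valued).
#' @param threshold Intensity at or above which a frame counts as active.
#' @return Integer 0/1 matrix, frames x channels.
#' @export
binarize_activation <- function(series, threshold = 1) {
  m <- unclass(series) >= threshold
  storage.mode(m) <- "integer"
  m
}

# longest run of TRUE in a logical vector (0 when empty/none)
longest_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Detect a mimicked expression inside one window
#'
#' TRUE iff, restricting the activation mask to the frames of the window,
#' some alternative AU set of the emotion's pattern has all its member AUs
#' simultaneously active for at least `min_run` consecutive frames.
#'
#' @param mask Binary activation matrix from [binarize_activation()].
#' @param pattern List of alternative AU-label vectors (one element of
#'   [emotion_patterns()]).
#' @param frames Integer vector of window frame indices (1-based, ascending).
#' @param min_run Minimum consecutive active frames (default 3).
#' @return Logical flag.
#' @export
detect_window <- function(mask, pattern, frames, min_run = 3L) {
  aus <- unique(unlist(pattern))
  unknown <- setdiff(aus, colnames(mask))
  if (length(unknown)) {
    stop("pattern references unknown AU channel(s): ",
         paste(unknown, collapse = ", "))
  }
  frames <- frames[frames >= 1L & frames <= nrow(mask)]
  if (!length(frames)) return(FALSE)
  for (alt in pattern) {
    joint <- mask[frames, alt, drop = FALSE]
    active <- rowSums(joint) == length(alt)
    if (longest_run(active) >= min_run) return(TRUE)
  }
  FALSE
}

#' Score one snippet's spontaneous mimicry in both windows
#'
#' @param series Raw participant [au_series()] of a spontaneous snippet.
#' @param emotion Target emotion of the stimulus.
#' @param windows A [mimicry_windows()].
#' @param patterns Emotion-pattern table, default [emotion_patterns()].
#' @param threshold Activation threshold, see [binarize_activation()].
#' @return List with logical `rfr` and `cfr` flags.
#' @export
detect_mimicry <- function(series, emotion, windows = mimicry_windows(),
                           patterns = emotion_patterns(), threshold = 1) {
  pattern <- patterns[[emotion]]
  if (is.null(pattern)) stop("no AU pattern for emotion ", dQuote(emotion))
  mask <- binarize_activation(series, threshold)
  fps <- series_fps(series)
  n <- nrow(mask)
  list(
    rfr = detect_window(mask, pattern,
                        window_frames(windows$rfr_ms, n, fps, FALSE),
                        windows$min_run),
    cfr = detect_window(mask, pattern,
                        window_frames(windows$cfr_ms, n, fps, TRUE),
                        windows$min_run)
  )
}

#' Per-embodiment spontaneous mimicry rates
#'
#' Aggregates snippet-level detections into the participant x embodiment x
#' window rate table used by the statistical stage: the number of mimicked
#' trials divided by the number of valid snippets for that embodiment.
#' Embodiments with no valid snippets for a participant are absent from the
#' table (excluded, not rated 0).
#'
#' @param outcomes Data frame with columns `participant_id`, `group`,
#'   `embodiment`, `valid` (logical), `rfr`, `cfr` (logical, may be NA on
#'   invalid snippets).
#' @return Data frame with one row per participant x embodiment x window:
#'   `participant_id`, `group`, `embodiment`, `window` ("RFR"/"CFR"),
#'   `n_valid`, `n_mimicked`, `rate`.
#' @export
mimicry_rates <- function(outcomes) {
  valid <- outcomes[outcomes$valid, , drop = FALSE]
  if (!nrow(valid)) {
    return(data.frame(participant_id = character(), group = character(),
                      embodiment = character(), window = character(),
                      n_valid = integer(), n_mimicked = integer(),
                      rate = numeric()))
  }
  out <- do.call(rbind, lapply(c(rfr = "rfr", cfr = "cfr"), function(w) {
    agg <- stats::aggregate(
      valid[[w]],
      by = valid[c("participant_id", "group", "embodiment")],
      FUN = function(x) c(n = length(x), k = sum(x))
    )
    data.frame(agg[c("participant_id", "group", "embodiment")],
               window = toupper(w),
               n_valid = as.integer(agg$x[, "n"]),
               n_mimicked = as.integer(agg$x[, "k"]))
  }))
  out$rate <- out$n_mimicked / out$n_valid
  rownames(out) <- NULL
  out[order(out$participant_id, out$embodiment, out$window), , drop = FALSE]
}
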