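#' Action Unit channel order
#'
#' The fixed set and order of FACS Action Unit channels carried by every
#' [au_series()]: AU1 (inner brow raiser), AU2 (outer brow raiser), AU4 (brow
#' lowerer), AU6 (cheek raiser), AU12 (lip corner puller), AU15 (lip corner
#' depressor), AU20 (lip stretcher), AU25 (lips part), AU26 (jaw drop).
#'
#' @return Character vector of the nine AU labels, in canonical order.
#' @export
au_channels <- function() {
  c("AU1", "AU2", "AU4", "AU6", "AU12", "AU15", "AU20", "AU25", "AU26")
}

#' Basic-emotion labels
#'
#' @return Character vector of the six basic emotions.
#' @export
emotions <- function() {
  c("happiness", "sadness", "surprise", "anger", "fear", "disgust")
}

#' AU patterns that count as a mimicked basic emotion
#'
#' For each basic emotion, the list of alternative AU sets any one of which,
#' when simultaneously active, counts as the target expression. Alternatives
#' are read disjunctively and the AUs within one alternative conjunctively:
#' happiness is mimicked by AU6 alone, AU12 alone, or AU6 and AU12 together;
#' fear by AU20 alone or by AU1, AU2 and AU4 together.
#'
#' @return Named list (one element per emotion) of lists of character vectors
#'   of AU labels.
#' @export
#' @examples
#' emotion_patterns()$anger
emotion_patterns <- function() {
  list(
    anger     = list("AU4"),
    disgust   = list(c("AU4", "AU25")),
    fear      = list("AU20", c("AU1", "AU2", "AU4")),
    happiness = list("AU6", "AU12", c("AU6", "AU12")),
    sadness   = list("AU1", "AU15", c("AU1", "AU4")),
    surprise  = list("AU26", c("AU1", "AU2"))
  )
}

#' Onset-apex-offset expression template
#'
#' Describes a posed facial-expression stimulus as a set of AU peak
#' intensities and a three-phase frame partition: a linear rise from neutral
#' to peak (onset), a hold at peak (apex), and a linear decay back to neutral
#' (offset). Defaults give a 5 s stimulus at 30 fps split 1 s / 3 s / 1 s.
#'
#' @param emotion One of [emotions()].
#' @param au_peaks Named numeric vector of peak ordinal intensities (0-5) for
#'   the AUs the expression recruits; names must be AU labels from
#'   [au_channels()]. Defaults to peak 4 on the union of the emotion's
#'   [emotion_patterns()] AU sets.
#' @param onset_frames,apex_frames,offset_frames Frame counts of the three
#'   phases; must sum to `total_frames`.
#' @param total_frames Total stimulus length in frames.
#' @return An object of class `expression_template`.
#' @export
#' @examples
#' expression_template("anger")
expression_template <- function(emotion,
                                au_peaks = NULL,
                                onset_frames = 30L,
                                apex_frames = 90L,
                                offset_frames = 30L,
                                total_frames = 150L) {
  emotion <- match.arg(emotion, emotions())
  if (is.null(au_peaks)) {
    aus <- unique(unlist(emotion_patterns()[[emotion]]))
    au_peaks <- stats::setNames(rep(4, length(aus)), aus)
  }
  if (is.null(names(au_peaks)) || !all(names(au_peaks) %in% au_channels())) {
    stop("au_peaks must be named with AU labels from au_channels()")
  }
  if (any(au_peaks < 0 | au_peaks > 5)) {
    stop("au_peaks must lie in [0, 5]")
  }
  if (onset_frames + apex_frames + offset_frames != total_frames) {
    stop("onset_frames + apex_frames + offset_frames must equal total_frames")
  }
  structure(
    list(
      emotion = emotion,
      au_peaks = au_peaks,
      onset_frames = as.integer(onset_frames),
      apex_frames = as.integer(apex_frames),
      offset_frames = as.integer(offset_frames),
      total_frames = as.integer(total_frames)
    ),
    class = "expression_template"
  )
}

#' Default stimulus templates for all six emotions
#'
#' @param ... Passed to [expression_template()] (frame partition overrides).
#' @return Named list of `expression_template` objects, one per emotion.
#' @export
default_templates <- function(...) {
  tpl <- lapply(emotions(), expression_template, ...)
  stats::setNames(tpl, emotions())
}
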