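#' AU intensity time series
#'
#' Container for one snippet's frames-by-channels matrix of facial Action
#' Unit intensities on the six-category ordinal scale (0 = neutral ... 5 =
#' maximum). Raw detector output is integer-valued; smoothing produces real
#' values on the same [0, 5] scale.
#'
#' @param values Numeric matrix, frames in rows, AU channels in columns.
#'   Columns must be named with (a subset of, in order) [au_channels()]; an
#'   unnamed 9-column matrix is accepted and labelled canonically.
#' @param fps Sampling rate in frames per second.
#' @param emotion Optional emotion label attached to stimulus/response series.
#' @return An `au_series` object: the matrix with `fps` (and optionally
#'   `emotion`) attributes.
#' @export
#' @examples
#' s <- au_series(matrix(0L, 150, 9), fps = 30)
#' n_frames(s)
au_series <- function(values, fps = 30, emotion = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("au_series needs at least one frame")
  if (is.null(colnames(values))) {
    if (ncol(values) != length(au_channels())) {
      stop("unnamed matrix must have ", length(au_channels()), " columns")
    }
    colnames(values) <- au_channels()
  }
  if (!all(colnames(values) %in% au_channels())) {
    stop("unknown AU channel(s): ",
         paste(setdiff(colnames(values), au_channels()), collapse = ", "))
  }
  if (anyNA(values) || any(values < 0) || any(values > 5)) {
    stop("AU intensities must lie in [0, 5] with no missing values")
  }
  if (fps <= 0) stop("fps must be positive")
  structure(values, fps = fps, emotion = emotion,
            class = c("au_series", "matrix", "array"))
}

#' @rdname au_series
#' @param x An `au_series`.
#' @export
n_frames <- function(x) nrow(x)

#' @rdname au_series
#' @export
series_fps <- function(x) attr(x, "fps")

#' @export
print.au_series <- function(x, ...) {
  cat(sprintf("<au_series> %d frames x %d channels @ %g fps%s\n",
              nrow(x), ncol(x), attr(x, "fps"),
              if (!is.null(attr(x, "emotion")))
                paste0(" [", attr(x, "emotion"), "]") else ""))
  invisible(x)
}

# rebuild an au_series around a new value matrix, keeping metadata
reseries <- function(values, like) {
  au_series(values, fps = attr(like, "fps"), emotion = attr(like, "emotion"))
}

#' Map detector intensity category codes to ordinal intensities
#'
#' The AU detector grades each frame into six categories following Ekman's
#' taxonomy: "N" (neutral), "A" (trace), "B" (slight), "C" (marked),
#' "D" (severe), "E" (maximum). These map to the ordinals 0-5.
#'
#' @param labels Character vector (or matrix) of category codes.
#' @return Integer vector (or matrix) of ordinal intensities 0-5.
#' @export
#' @examples
#' map_intensity_categories(c("N", "A", "B", "C", "D", "E"))
map_intensity_categories <- function(labels) {
  codes <- c(N = 0L, A = 1L, B = 2L, C = 3L, D = 4L, E = 5L)
  flat <- as.character(labels)
  bad <- which(!flat %in% names(codes))
  if (length(bad)) {
    stop("unknown intensity category code ", dQuote(flat[bad[1]]),
         " at position ", bad[1])
  }
  out <- unname(codes[flat])
  if (is.matrix(labels)) {
    out <- matrix(out, nrow(labels), ncol(labels), dimnames = dimnames(labels))
  }
  out
}

#' Map ordinal intensities back to category codes
#'
#' Inverse of [map_intensity_categories()].
#'
#' @param x Integer vector of ordinals in 0-5.
#' @return Character vector of codes N/A/B/C/D/E.
#' @export
unmap_intensity_categories <- function(x) {
  if (any(!x %in% 0:5)) stop("ordinal intensities must be integers in [0, 5]")
  c("N", "A", "B", "C", "D", "E")[x + 1L]
}

#' Low-pass filter an AU series with a centered moving average
#'
#' Each frame is replaced, per channel, by the mean of the frames inside a
#' centered window. For the default even window of 10 samples the window at
#' frame t spans frames t-5 .. t+4; at the series edges the window shrinks to
#' the available frames (no padding), so output length equals input length.
#'
#' @param series An [au_series()].
#' @param window Window size in samples (default 10).
#' @return A smoothed `au_series` with real-valued intensities in [0, 5].
#' @export
#' @examples
#' s <- au_series(matrix(rep(c(0L, 5L), each = 5), 10, 9), fps = 30)
#' smooth_au(s)[5, 1]
smooth_au <- function(series, window = 10L) {
  n <- nrow(series)
  if (n == 0L) stop("cannot smooth an empty series")
  window <- as.integer(window)
  if (window < 1L || window > n) stop("window must be in [1, n_frames]")
  if (window == 1L) return(series)
  left <- window %/% 2L            # frames before t
  right <- window - left - 1L      # frames after t
  t <- seq_len(n)
  lo <- pmax(t - left, 1L)
  hi <- pmin(t + right, n)
  # running means per channel via cumulative sums with shrinking edges
  vals <- apply(unclass(series), 2L, function(col) {
    cs <- c(0, cumsum(col))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  vals <- matrix(vals, nrow = n, dimnames = dimnames(series))
  reseries(vals, series)
}

#' Remove instructed-mimicry buffer frames
#'
#' Instructed-mimicry snippets are cut with a 1 s buffer (30 frames at
#' 30 fps) before the first and after the last mimicry frame; those buffers
#' are dropped before analysis. A snippet too short to contain anything
#' beyond its buffers is not an error but unusable: `NULL` is returned and
#' the caller marks the snippet invalid.
#'
#' @param series An [au_series()].
#' @param buffer Buffer length in frames at each end (default 30).
#' @return The trimmed `au_series`, or `NULL` when `n_frames <= 2 * buffer`.
#' @export
trim_instructed_buffers <- function(series, buffer = 30L) {
  buffer <- as.integer(buffer)
  if (buffer < 0L) stop("buffer must be non-negative")
  if (buffer == 0L) return(series)
  n <- nrow(series)
  if (n <= 2L * buffer) return(NULL)
  reseries(unclass(series)[(buffer + 1L):(n - buffer), , drop = FALSE], series)
}
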