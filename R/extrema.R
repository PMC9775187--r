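#' Detect candidate peaks and troughs
#'
#' Finds the local extrema of a waveform while ignoring fluctuations that
#' persist only over a small window: sample `i` is a peak if it is the
#' maximum over `[i - m, i + m]` (window truncated at the record ends) and is
#' strictly larger than at least one immediate neighbour; for an exact tie
#' (plateau) only the earliest index is reported. Troughs are the peaks of
#' the negated signal. Small `m` keeps genuine physiological turning points
#' while discarding single-sample noise wiggles.
#'
#' @param w An `aep_waveform` (or a plain numeric vector).
#' @param m Half-window in samples (`>= 1`); the waveform must be longer
#'   than `2 * m`.
#' @return An `extrema_set`: list with sorted integer vectors `peaks` and
#'   `troughs` (1-based sample indices) and the window `m`.
#' @export
find_local_extrema <- function(w, m = 4L) {
  x <- if (inherits(w, "aep_waveform")) w$amplitudes else as.numeric(w)
  m <- as.integer(m)
  if (m < 1L) stop("find_local_extrema: m must be >= 1", call. = FALSE)
  n <- length(x)
  if (n <= 2L * m) {
    stop(sprintf(
      "find_local_extrema: window m = %d too large for %d samples", m, n
    ), call. = FALSE)
  }
  structure(
    list(peaks = windowed_maxima(x, m), troughs = windowed_maxima(-x, m),
         window_m = m),
    class = "extrema_set"
  )
}

# indices i with x[i] == max(x[i-m .. i+m]) (truncated windows), strictly
# above at least one immediate neighbour, earliest index on plateaus
windowed_maxima <- function(x, m) {
  n <- length(x)
  win_max <- vapply(seq_len(n), function(i) {
    max(x[max(1L, i - m):min(n, i + m)])
  }, numeric(1))
  is_cand <- x == win_max
  keep <- logical(n)
  for (i in which(is_cand)) {
    lo <- max(1L, i - m)
    # plateau rule: an equal value earlier in the window claims the extremum
    if (i > lo && max(x[lo:(i - 1L)]) == x[i]) next
    strict_nb <- (i > 1L && x[i - 1L] < x[i]) || (i < n && x[i + 1L] < x[i])
    keep[i] <- strict_nb
  }
  which(keep)
}

#' @export
print.extrema_set <- function(x, ...) {
  cat(sprintf("<extrema_set> m = %d: %d peaks, %d troughs\n",
              x$window_m, length(x$peaks), length(x$troughs)))
  invisible(x)
}
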