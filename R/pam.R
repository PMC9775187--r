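#' Screen an AMLR waveform for a post-auricular-muscle artifact
#'
#' The PAM reflex contaminates middle-latency recordings as a sharp spike in
#' the 13-15 ms range -- before the basal Pa component appears -- with an
#' amplitude much larger than Pa's. The screen flags a recording when any
#' candidate extremum (either polarity) inside the PAM window has absolute
#' amplitude at least `pam_ratio` times the Pa reference amplitude. The
#' reference is the annotated Pa amplitude; when Pa is `NA`, the largest
#' absolute amplitude inside the Pa core interval is used instead, and if
#' that region is identically zero the waveform's RMS takes its place.
#'
#' @param w A filtered AMLR `aep_waveform`.
#' @param ex The `extrema_set` computed from `w`.
#' @param ann The `aep_annotation` computed from `w` (Pa may be `NA`).
#' @param pam_window_ms Length-2 numeric, the latency window searched for
#'   the spike (default 13-15 ms).
#' @param pam_ratio Amplitude ratio threshold (default 2).
#' @param cfg Optional [rule_config()] supplying the Pa core interval and
#'   defaults for the window and ratio.
#' @return A `pam_result`: list with `detected`, and when detected
#'   `spike_latency_ms`, `spike_amplitude_uv`, `ratio_to_pa`.
#' @export
detect_pam <- function(w, ex, ann,
                       pam_window_ms = cfg$pam_window_ms,
                       pam_ratio = cfg$pam_ratio,
                       cfg = default_rule_config("AMLR")) {
  check_annotation_input(w, "AMLR")
  stopifnot(inherits(ex, "extrema_set"), inherits(ann, "aep_annotation"))

  ref <- abs(ann$waves$Pa$amplitude_uv)
  if (is.na(ref)) {
    core <- cfg$interval_rules$Pa$core_ms
    in_core <- w$times_ms >= core[1] & w$times_ms <= core[2]
    ref <- max(abs(w$amplitudes[in_core]))
    if (ref == 0) ref <- sqrt(mean(w$amplitudes^2))
  }

  idx <- sort(c(ex$peaks, ex$troughs))
  lat <- w$times_ms[idx]
  in_win <- lat >= pam_window_ms[1] & lat <= pam_window_ms[2]
  idx <- idx[in_win]
  hit <- if (length(idx) && ref > 0) {
    abs(w$amplitudes[idx]) >= pam_ratio * ref
  } else {
    logical(0)
  }

  if (any(hit)) {
    best <- idx[hit][which.max(abs(w$amplitudes[idx[hit]]))]
    structure(list(detected = TRUE,
                   spike_latency_ms = w$times_ms[best],
                   spike_amplitude_uv = w$amplitudes[best],
                   ratio_to_pa = abs(w$amplitudes[best]) / ref),
              class = "pam_result")
  } else {
    structure(list(detected = FALSE,
                   spike_latency_ms = NA_real_,
                   spike_amplitude_uv = NA_real_,
                   ratio_to_pa = NA_real_),
              class = "pam_result")
  }
}

#' @export
print.pam_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "<pam_result> DETECTED: spike at %.2f ms, %+.2f uV (%.2fx Pa)\n",
      x$spike_latency_ms, x$spike_amplitude_uv, x$ratio_to_pa
    ))
  } else {
    cat("<pam_result> no PAM artifact detected\n")
  }
  invisible(x)
}
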