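#' Average the two acquisition buffers into a microvolt waveform
#'
#' The displayed AEP waveform is the mean of the two interleaved sweep
#' buffers, converted from raw units to microvolts:
#' `amplitude[i] = raw_to_microvolt * (buffer_a[i] + buffer_b[i]) / 2`.
#' The stimulus-locked time axis starts at 0 ms at the first sample (the
#' acquisition system starts the stimulus early so the first stored sample
#' coincides with stimulus completion; `prestimulus_samples` is metadata and
#' does not shift the axis).
#'
#' @param rec A [raw_recording()].
#' @return An `aep_waveform`: list with `subtype`, `amplitudes` (microvolt),
#'   `times_ms`, `sample_rate`, `filtered = FALSE` and `source_id`.
#' @export
average_buffers <- function(rec) {
  validate_raw_recording(rec)
  amp <- rec$raw_to_microvolt * (rec$buffer_a + rec$buffer_b) / 2
  new_waveform(rec$subtype, amp, rec$sample_rate,
               filtered = FALSE, source_id = rec$patient_id)
}

new_waveform <- function(subtype, amplitudes, sample_rate, filtered,
                         source_id = "") {
  structure(
    list(
      subtype = match.arg(subtype, SUBTYPES),
      amplitudes = as.numeric(amplitudes),
      times_ms = build_time_axis(length(amplitudes), sample_rate),
      sample_rate = sample_rate,
      filtered = isTRUE(filtered),
      source_id = as.character(source_id)
    ),
    class = "aep_waveform"
  )
}

#' @export
print.aep_waveform <- function(x, ...) {
  cat(sprintf(
    "<aep_waveform> %s, %d samples @ %g Hz (0-%.4g ms), %s\n",
    x$subtype, length(x$amplitudes), x$sample_rate,
    max(x$times_ms), if (x$filtered) "filtered" else "unfiltered"
  ))
  invisible(x)
}

#' Stimulus-locked time axis
#'
#' @param n_samples Number of samples (> 0).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return Numeric vector of timestamps in ms: `1000 * (0:(n-1)) / rate`.
#' @export
build_time_axis <- function(n_samples, sample_rate) {
  stopifnot(n_samples > 0, sample_rate > 0)
  1000 * (seq_len(n_samples) - 1) / sample_rate
}

#' Visual display filter specification
#'
#' Clinicians view and annotate AEPs through additional band-limiting
#' "visual display filters" on top of the acquisition filters. The low-pass
#' stage is a linear-phase FIR design and the high-pass stage a Butterworth
#' design; with `zero_phase = TRUE` both are applied forward-backward so that
#' extremum latencies, the measured quantity, are not shifted.
#'
#' @param low_pass_hz Low-pass cutoff in Hz.
#' @param high_pass_hz High-pass cutoff in Hz (must be below `low_pass_hz`).
#' @param fir_order FIR filter order for the low-pass stage.
#' @param butter_order Butterworth order for the high-pass stage.
#' @param zero_phase Apply both stages forward-backward.
#' @return A `display_filter_spec` object.
#' @export
display_filter_spec <- function(low_pass_hz, high_pass_hz,
                                fir_order = 100L, butter_order = 2L,
                                zero_phase = TRUE) {
  stopifnot(high_pass_hz > 0, low_pass_hz > high_pass_hz,
            fir_order >= 2, butter_order >= 1)
  structure(
    list(low_pass_hz = low_pass_hz, high_pass_hz = high_pass_hz,
         fir_order = as.integer(fir_order),
         butter_order = as.integer(butter_order),
         zero_phase = isTRUE(zero_phase)),
    class = "display_filter_spec"
  )
}

#' Default display filters per AEP subtype
#'
#' ABR: 150-1500 Hz; AMLR: 15-100 Hz, matching the preliminary display
#' settings of the standard clinical setup.
#'
#' @param subtype `"ABR"` or `"AMLR"`.
#' @inheritParams display_filter_spec
#' @return A [display_filter_spec()].
#' @export
default_filter_spec <- function(subtype, fir_order = 100L, butter_order = 2L,
                                zero_phase = TRUE) {
  switch(match.arg(subtype, SUBTYPES),
    ABR = display_filter_spec(1500, 150, fir_order, butter_order, zero_phase),
    AMLR = display_filter_spec(100, 15, fir_order, butter_order, zero_phase)
  )
}

# Odd (point-symmetric) reflection padding keeps the signal and its first
# difference continuous at the boundaries, so filter edge transients decay
# inside the padding instead of spawning spurious extrema in the epoch.
reflect_pad <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  if (n_pad < 1L) return(list(x = x, n_pad = 0L))
  left <- 2 * x[1] - x[(n_pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - n_pad)]
  list(x = c(left, x, right), n_pad = n_pad)
}

apply_one_filter <- function(x, flt, zero_phase) {
  if (zero_phase) {
    as.numeric(signal::filtfilt(flt, x))
  } else {
    as.numeric(signal::filter(flt, x))
  }
}

#' Apply visual display filters to a waveform
#'
#' Applies the FIR low-pass and Butterworth high-pass stages of `spec` to an
#' unfiltered waveform. The input is reflect-padded by one filter length
#' before filtering and trimmed afterwards, so length and time axis are
#' preserved exactly.
#'
#' @param w An unfiltered `aep_waveform` from [average_buffers()].
#' @param spec A [display_filter_spec()]; defaults to the subtype's standard
#'   display settings.
#' @return The filtered `aep_waveform` (`filtered = TRUE`).
#' @export
apply_display_filters <- function(w, spec = default_filter_spec(w$subtype)) {
  stopifnot(inherits(w, "aep_waveform"), inherits(spec, "display_filter_spec"))
  if (w$filtered) {
    stop("apply_display_filters: waveform is already filtered", call. = FALSE)
  }
  nyquist <- w$sample_rate / 2
  if (spec$low_pass_hz >= nyquist) {
    stop(sprintf(
      "display filter misconfigured: low-pass cutoff %g Hz >= Nyquist %g Hz",
      spec$low_pass_hz, nyquist
    ), call. = FALSE)
  }

  lp <- signal::fir1(spec$fir_order, spec$low_pass_hz / nyquist, type = "low")
  hp <- signal::butter(spec$butter_order, spec$high_pass_hz / nyquist,
                       type = "high")

  # baseline-correct first: the high-pass removes DC anyway, and taking the
  # mean out before padding avoids a step transient at the record ends
  x <- w$amplitudes - mean(w$amplitudes)
  # pad by the longer of the FIR length and the high-pass transient scale
  pad_len <- max(spec$fir_order,
                 ceiling(8 * w$sample_rate / (2 * pi * spec$high_pass_hz)))
  padded <- reflect_pad(x, pad_len)
  y <- apply_one_filter(padded$x, signal::Ma(lp), spec$zero_phase)
  y <- apply_one_filter(y, hp, spec$zero_phase)
  if (!spec$zero_phase) {
    # compensate the FIR stage's known linear-phase group delay so causal
    # mode stays comparable on latency; the IIR stage's delay is left as-is
    d <- spec$fir_order / 2
    y <- c(y[-seq_len(d)], rep(y[length(y)], d))
  }
  keep <- seq.int(padded$n_pad + 1L, padded$n_pad + length(w$amplitudes))
  out <- w
  out$amplitudes <- y[keep]
  out$filtered <- TRUE
  out
}
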