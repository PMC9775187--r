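#' Construct a raw AEP recording
#'
#' A `raw_recording` holds the content of one exported epoch before any
#' averaging or scaling: the two interleaved sweep buffers of the acquisition
#' system, the sampling metadata needed to rebuild the stimulus-locked time
#' axis, and (optionally) gold-standard wave positions set by a clinician.
#'
#' @param subtype `"ABR"` or `"AMLR"`.
#' @param buffer_a,buffer_b Numeric vectors of raw amplitude values, equal
#'   length. The displayed waveform is the average of the two buffers.
#' @param sample_rate Sampling rate in Hz.
#' @param prestimulus_samples Number of samples recorded before stimulus
#'   onset. Carried as metadata only: the acquisition system is calibrated so
#'   that the first stored sample coincides with stimulus completion, so the
#'   time axis starts at 0.
#' @param raw_to_microvolt Multiplicative factor converting raw buffer units
#'   to microvolts.
#' @param stimulus_intensity Stimulus intensity in dB nHL.
#' @param ear `"left"`, `"right"` or `"unknown"`.
#' @param patient_id Opaque identifier string.
#' @param gold_waves Optional named integer vector of 1-based sample indices,
#'   one per annotated wave label (e.g. `c(I = 46, III = 106, V = 166)`), or
#'   `NULL` when the recording carries no annotation.
#'
#' @return An object of class `raw_recording`.
#' @seealso [read_recording_xml()], [average_buffers()]
#' @export
raw_recording <- function(subtype, buffer_a, buffer_b, sample_rate,
                          prestimulus_samples = 0L, raw_to_microvolt = 1,
                          stimulus_intensity = NA_real_, ear = "unknown",
                          patient_id = "", gold_waves = NULL) {
  rec <- structure(
    list(
      subtype = match.arg(subtype, SUBTYPES),
      buffer_a = as.numeric(buffer_a),
      buffer_b = as.numeric(buffer_b),
      sample_rate = as.numeric(sample_rate),
      prestimulus_samples = as.integer(prestimulus_samples),
      raw_to_microvolt = as.numeric(raw_to_microvolt),
      stimulus_intensity = as.numeric(stimulus_intensity),
      ear = match.arg(ear, c("left", "right", "unknown")),
      patient_id = as.character(patient_id),
      gold_waves = if (is.null(gold_waves)) NULL else {
        gw <- as.integer(round(gold_waves))
        names(gw) <- names(gold_waves)
        gw
      }
    ),
    class = "raw_recording"
  )
  validate_raw_recording(rec)
  rec
}

#' Validate a raw recording's invariants
#'
#' Checks buffer lengths, sampling metadata and gold wave indices; stops with
#' an informative error on the first violation.
#'
#' @param rec A [raw_recording()] object.
#' @return `rec`, invisibly.
#' @export
validate_raw_recording <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- length(rec$buffer_a)
  if (n == 0L) {
    stop("raw_recording: buffers must be non-empty", call. = FALSE)
  }
  if (length(rec$buffer_b) != n) {
    stop(sprintf(
      "raw_recording: buffer length mismatch (A has %d samples, B has %d)",
      n, length(rec$buffer_b)
    ), call. = FALSE)
  }
  if (!is.finite(rec$sample_rate) || rec$sample_rate <= 0) {
    stop("raw_recording: sample_rate must be > 0", call. = FALSE)
  }
  if (is.na(rec$prestimulus_samples) || rec$prestimulus_samples < 0L) {
    stop("raw_recording: prestimulus_samples must be >= 0", call. = FALSE)
  }
  if (!is.finite(rec$raw_to_microvolt)) {
    stop("raw_recording: raw_to_microvolt must be finite", call. = FALSE)
  }
  gw <- rec$gold_waves
  if (!is.null(gw)) {
    if (is.null(names(gw)) || any(!nzchar(names(gw)))) {
      stop("raw_recording: gold_waves must be a named vector", call. = FALSE)
    }
    bad <- names(gw)[!names(gw) %in% subtype_waves(rec$subtype)]
    if (length(bad)) {
      stop(sprintf(
        "raw_recording: gold wave label(s) %s not valid for subtype %s",
        paste(bad, collapse = ", "), rec$subtype
      ), call. = FALSE)
    }
    if (any(gw < 1L | gw > n)) {
      stop("raw_recording: gold wave sample index out of range", call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %s, %d samples @ %g Hz, patient '%s', ear %s\n",
    x$subtype, length(x$buffer_a), x$sample_rate, x$patient_id, x$ear
  ))
  if (!is.null(x$gold_waves)) {
    cat("  gold waves:",
        paste(sprintf("%s=%d", names(x$gold_waves), x$gold_waves),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Gold-standard annotation of a recording
#'
#' Converts the `gold_waves` sample indices carried by a recording into an
#' `aep_annotation` (latencies from the stimulus-locked time axis, amplitudes
#' from the averaged waveform), so clinician positions can be scored with
#' [compute_match_rates()] exactly like automated annotations.
#'
#' @param rec A [raw_recording()] with `gold_waves` set (waves absent from
#'   the mapping are `NA` in the result).
#' @return An `aep_annotation` object.
#' @export
gold_annotation <- function(rec) {
  validate_raw_recording(rec)
  w <- average_buffers(rec)
  waves <- stats::setNames(
    vector("list", length(subtype_waves(rec$subtype))),
    subtype_waves(rec$subtype)
  )
  for (lbl in names(waves)) {
    idx <- if (!is.null(rec$gold_waves)) unname(rec$gold_waves[lbl]) else NA
    waves[[lbl]] <- if (is.na(idx)) wave_na() else wave_at(w, idx)
  }
  new_annotation(rec$subtype, waves, source_id = rec$patient_id)
}
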