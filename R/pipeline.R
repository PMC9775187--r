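#' Annotate a list of recordings
#'
#' Runs [annotate_recording()] on each element, dispatching on each
#' recording's subtype and per-subtype configuration.
#'
#' @param recordings List of [raw_recording()] objects.
#' @param configs Named list of [rule_config()]s (`ABR`, `AMLR`).
#' @return Named list of `aep_annotation` objects (names follow the input).
#' @export
annotate_recordings <- function(recordings,
                                configs = list(ABR = default_rule_config("ABR"),
                                               AMLR = default_rule_config("AMLR"))) {
  anns <- lapply(recordings, function(rec) {
    annotate_recording(rec, configs[[rec$subtype]])$annotation
  })
  names(anns) <- names(recordings)
  anns
}

#' Score an annotated benchmark against its ground truth
#'
#' Annotates every benchmark recording, optionally screens AMLR recordings
#' for PAM artifacts and drops the flagged ones (screen, drop, re-score
#' protocol), and computes per-wave match rates against the generator's
#' gold positions.
#'
#' @param bench Output of [generate_benchmark()] (or any list with
#'   `recordings`; gold annotations are taken from each recording's
#'   `gold_waves`).
#' @param cfg [rule_config()] for the benchmark's subtype.
#' @param tolerance Match tolerance in samples.
#' @param exclude_pam Screen with [detect_pam()] and drop detections before
#'   scoring (AMLR only).
#' @return List with `report` (a [compute_match_rates()] result), `details`
#'   (per-wave deviations), `n_scored`, and `dropped` (ids removed by the
#'   PAM screen).
#' @export
evaluate_benchmark <- function(bench, cfg = NULL, tolerance = 4L,
                               exclude_pam = FALSE) {
  recs <- bench$recordings
  stopifnot(length(recs) >= 1)
  subtype <- recs[[1]]$subtype
  if (is.null(cfg)) cfg <- default_rule_config(subtype)

  dropped <- character(0)
  anns <- vector("list", length(recs))
  keep <- logical(length(recs))
  for (i in seq_along(recs)) {
    res <- annotate_recording(recs[[i]], cfg)
    anns[[i]] <- res$annotation
    keep[i] <- TRUE
    if (exclude_pam && subtype == "AMLR") {
      pam <- detect_pam(res$waveform, res$extrema, res$annotation, cfg = cfg)
      if (pam$detected) {
        keep[i] <- FALSE
        dropped <- c(dropped, recs[[i]]$patient_id)
      }
    }
  }
  names(anns) <- names(recs)
  gold <- lapply(recs, gold_annotation)
  report <- compute_match_rates(anns[keep], gold[keep], tolerance)
  list(report = report,
       details = match_details(anns[keep], gold[keep], tolerance),
       n_scored = sum(keep), dropped = dropped)
}
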