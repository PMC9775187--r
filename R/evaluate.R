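#' Convert a sample deviation to milliseconds
#'
#' Each exported epoch holds 450 samples regardless of subtype, spanning
#' 15 ms (ABR) or 150 ms (AMLR), so a deviation of `k` samples corresponds
#' to `k * window / 450` ms: the standard +/-4-sample acceptance tolerance
#' is about 0.13 ms for ABR and about 1.33 ms for AMLR.
#'
#' @param k Deviation in samples (`>= 0`).
#' @param subtype `"ABR"` or `"AMLR"`.
#' @return Deviation in ms.
#' @export
sample_deviation_to_ms <- function(k, subtype) {
  stopifnot(all(k >= 0))
  k * subtype_window_ms(subtype) / EPOCH_SAMPLES
}

annotations_to_df <- function(anns, ids = NULL) {
  if (inherits(anns, "aep_annotation")) anns <- list(anns)
  if (is.null(ids)) {
    ids <- names(anns)
    if (is.null(ids)) ids <- as.character(seq_along(anns))
  }
  rows <- lapply(seq_along(anns), function(i) {
    ann <- anns[[i]]
    data.frame(
      id = ids[[i]],
      subtype = ann$subtype,
      wave = names(ann$waves),
      sample = vapply(ann$waves, function(wv) wv$index, integer(1)),
      latency_ms = vapply(ann$waves, function(wv) wv$latency_ms, numeric(1)),
      amplitude_uv = vapply(ann$waves, function(wv) wv$amplitude_uv,
                            numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-wave deviation details between predicted and gold annotations
#'
#' @inheritParams compute_match_rates
#' @return Data frame with one row per (recording, wave) evaluable pair:
#'   predicted and gold sample indices, deviation in samples and ms, and a
#'   `matched` flag.
#' @export
match_details <- function(pred, gold, tolerance = 4L) {
  pd <- annotations_to_df(pred)
  gd <- annotations_to_df(gold)
  if (nrow(pd) != nrow(gd) ||
      !identical(pd$id, gd$id) || !identical(pd$wave, gd$wave) ||
      !identical(pd$subtype, gd$subtype)) {
    stop("match_details: predicted and gold annotation lists are not aligned",
         call. = FALSE)
  }
  dev <- abs(pd$sample - gd$sample)
  data.frame(
    id = pd$id, subtype = pd$subtype, wave = pd$wave,
    pred_sample = pd$sample, gold_sample = gd$sample,
    deviation_samples = dev,
    deviation_ms = ifelse(is.na(dev), NA_real_,
                          vapply(seq_along(dev), function(i) {
                            if (is.na(dev[i])) NA_real_
                            else sample_deviation_to_ms(dev[i], pd$subtype[i])
                          }, numeric(1))),
    gold_present = !is.na(gd$sample),
    matched = !is.na(pd$sample) & !is.na(gd$sample) & dev <= tolerance,
    stringsAsFactors = FALSE
  )
}

#' Match rates of automated annotations against a gold standard
#'
#' A wave is evaluable when the gold annotation marks it; it counts as
#' matched when the automated annotation also marks it within `tolerance`
#' samples (boundary inclusive) of the gold position. A predicted `NA`
#' against a marked gold wave counts as a miss; waves the gold standard
#' leaves unmarked are excluded from the denominator (set
#' `drop_gold_na = FALSE` to count every recording as evaluable instead).
#'
#' @param pred,gold Lists of `aep_annotation` objects, aligned one-to-one by
#'   recording (same order, same subtypes; names, if set, are used as ids).
#' @param tolerance Acceptance tolerance in samples (default 4).
#' @param drop_gold_na Exclude gold-`NA` waves from the denominator
#'   (default `TRUE`).
#' @return A `match_report`: data frame with one row per wave label
#'   (`wave`, `n_evaluable`, `n_matched`, `match_rate` in percent) carrying
#'   `tolerance_samples` and `tolerance_ms` attributes.
#' @export
compute_match_rates <- function(pred, gold, tolerance = 4L,
                                drop_gold_na = TRUE) {
  det <- match_details(pred, gold, tolerance)
  subtype <- det$subtype[1]
  labels <- subtype_waves(subtype)
  rows <- lapply(labels, function(lbl) {
    d <- det[det$wave == lbl, ]
    if (drop_gold_na) d <- d[d$gold_present, ]
    n_eval <- nrow(d)
    n_match <- sum(d$matched)
    data.frame(wave = lbl, n_evaluable = n_eval, n_matched = n_match,
               match_rate = if (n_eval > 0) 100 * n_match / n_eval
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            tolerance_samples = as.integer(tolerance),
            tolerance_ms = sample_deviation_to_ms(tolerance, subtype),
            subtype = subtype,
            class = c("match_report", "data.frame"))
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %s, tolerance %d samples (%.2f ms)\n",
              attr(x, "subtype"), attr(x, "tolerance_samples"),
              attr(x, "tolerance_ms")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
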