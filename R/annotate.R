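# Annotation engine
# -----------------
# Stage-1 interval tables and stage-2 combinatorial selection rules. ABR
# peaks are resolved in the order I -> III -> V (each later search
# constrained by interpeak gaps against the earlier finds), then II and IV
# as assisting waves strictly between their neighbours. AMLR starts from the
# basal Pa component (maximum amplitude inside its interval), then Na before
# it, Nb after it with time-distance priority, and Pb from the Pa/Nb time
# stamps. A wave with no qualifying candidate is NA and never blocks the
# remaining searches.

wave_na <- function() {
  list(index = NA_integer_, latency_ms = NA_real_, amplitude_uv = NA_real_)
}

wave_at <- function(w, idx) {
  list(index = as.integer(idx),
       latency_ms = w$times_ms[idx],
       amplitude_uv = w$amplitudes[idx])
}

new_annotation <- function(subtype, waves, source_id = "") {
  structure(list(subtype = subtype, waves = waves, source_id = source_id),
            class = "aep_annotation")
}

#' @export
print.aep_annotation <- function(x, ...) {
  cat(sprintf("<aep_annotation> %s '%s'\n", x$subtype, x$source_id))
  for (lbl in names(x$waves)) {
    wv <- x$waves[[lbl]]
    if (is.na(wv$index)) {
      cat(sprintf("  %-3s NA\n", lbl))
    } else {
      cat(sprintf("  %-3s sample %3d  %6.2f ms  %+.3f uV\n",
                  lbl, wv$index, wv$latency_ms, wv$amplitude_uv))
    }
  }
  invisible(x)
}

#' One-row data frame view of an annotation
#'
#' @param x An `aep_annotation`.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return Data frame with `<wave>_sample`, `<wave>_latency_ms`,
#'   `<wave>_amplitude_uv` columns per wave label.
#' @export
as.data.frame.aep_annotation <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  cols <- list(source_id = x$source_id, subtype = x$subtype)
  for (lbl in names(x$waves)) {
    wv <- x$waves[[lbl]]
    cols[[paste0(lbl, "_sample")]] <- wv$index
    cols[[paste0(lbl, "_latency_ms")]] <- wv$latency_ms
    cols[[paste0(lbl, "_amplitude_uv")]] <- wv$amplitude_uv
  }
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# A selection constraint ties a candidate to an already-resolved anchor:
# candidate latency - anchor latency must fall in `gap` when direction is
# "after", anchor - candidate in `gap` when "before". NA anchors are skipped
# upstream. `bounds` constraints restrict latency to an open interval.
anchor_constraint <- function(anchor_ms, rule, direction = c("after", "before")) {
  list(type = "gap", anchor_ms = anchor_ms, gap = rule$allowed_gap_ms,
       direction = match.arg(direction))
}

bounds_constraint <- function(lower_ms = -Inf, upper_ms = Inf) {
  list(type = "bounds", lower = lower_ms, upper = upper_ms)
}

satisfies <- function(lat, con) {
  if (con$type == "bounds") return(lat > con$lower & lat < con$upper)
  gap <- if (con$direction == "after") lat - con$anchor_ms else con$anchor_ms - lat
  gap >= con$gap[1] & gap <= con$gap[2]
}

#' Select one wave of interest among candidate extrema
#'
#' Implements the stage-2 priority rule for a single wave: among candidates
#' of the rule's polarity whose latency lies in the expanded range and which
#' satisfy all active inter-wave constraints, a candidate in the core
#' (normal) range with the most extreme amplitude wins, unless an
#' expanded-only candidate is "much larger" -- its absolute amplitude at
#' least `amplitude_override_ratio` times the best core amplitude. With
#' `mode = "time"`, feasible candidates are ranked by closeness of their gap
#' to the anchor to the midpoint of the allowed gap window (time-related
#' conditions take priority over amplitude), with amplitude as tie-break;
#' candidates below `min_rel_amplitude` of the largest feasible amplitude
#' are not eligible for time ranking. Ties break toward the earliest
#' latency. No qualifying candidate gives `NA`.
#'
#' @param candidates An `extrema_set` from [find_local_extrema()].
#' @param w The filtered `aep_waveform` the candidates came from.
#' @param rule A [wave_interval_rule()].
#' @param constraints List of constraints built from resolved anchors (see
#'   [annotate_abr()] / [annotate_amlr()]); constraints whose anchor is NA
#'   must be dropped by the caller.
#' @param cfg A [rule_config()].
#' @param mode `"amplitude"` (default priority rule) or `"time"`
#'   (time-distance priority, used for AMLR Nb/Pb).
#' @param time_anchor For `mode = "time"`: the gap constraint (from
#'   `constraints`) whose midpoint anchors the ranking.
#' @return Integer sample index of the selected extremum, or `NA`.
#' @export
select_wave <- function(candidates, w, rule, constraints = list(),
                        cfg, mode = c("amplitude", "time"),
                        time_anchor = NULL) {
  mode <- match.arg(mode)
  idx <- if (rule$polarity == "peak") candidates$peaks else candidates$troughs
  if (length(idx) == 0L) return(NA_integer_)
  lat <- w$times_ms[idx]
  amp <- w$amplitudes[idx]

  ok <- lat >= rule$expanded_ms[1] & lat <= rule$expanded_ms[2]
  if (!is.na(rule$hard_cap_ms)) ok <- ok & lat <= rule$hard_cap_ms
  for (con in constraints) ok <- ok & satisfies(lat, con)
  if (!any(ok)) return(NA_integer_)
  idx <- idx[ok]; lat <- lat[ok]; amp <- amp[ok]

  in_core <- lat >= rule$core_ms[1] & lat <= rule$core_ms[2]
  sgn <- if (rule$polarity == "peak") 1 else -1

  if (mode == "time") {
    if (is.null(time_anchor) || time_anchor$type != "gap") {
      stop("select_wave: time mode needs a gap constraint as time_anchor",
           call. = FALSE)
    }
    big <- abs(amp) >= cfg$min_rel_amplitude * max(abs(amp))
    idx <- idx[big]; lat <- lat[big]; amp <- amp[big]; in_core <- in_core[big]
    pool <- if (any(in_core)) which(in_core) else seq_along(idx)
    mid <- mean(time_anchor$gap)
    gap <- if (time_anchor$direction == "after") {
      lat[pool] - time_anchor$anchor_ms
    } else {
      time_anchor$anchor_ms - lat[pool]
    }
    ord <- order(abs(gap - mid), -sgn * amp[pool], lat[pool])
    return(idx[pool[ord[1L]]])
  }

  pick_extreme <- function(sel) {
    ord <- order(-sgn * amp[sel], lat[sel])
    sel[ord[1L]]
  }
  if (any(in_core)) {
    best_core <- pick_extreme(which(in_core))
    exp_only <- which(!in_core)
    if (length(exp_only)) {
      best_exp <- pick_extreme(exp_only)
      # "much larger" is judged in the wave's polarity direction, so a
      # negative ripple can never displace a genuine (small) peak
      e_core <- sgn * amp[best_core]
      e_exp <- sgn * amp[best_exp]
      if (e_exp > e_core &&
          e_exp >= cfg$amplitude_override_ratio * max(e_core, 0)) {
        return(idx[best_exp])
      }
    }
    return(idx[best_core])
  }
  idx[pick_extreme(seq_along(idx))]
}

check_annotation_input <- function(w, subtype) {
  stopifnot(inherits(w, "aep_waveform"))
  if (w$subtype != subtype) {
    stop(sprintf("annotate: expected a %s waveform, got %s", subtype,
                 w$subtype), call. = FALSE)
  }
  if (!w$filtered) {
    stop("annotate: waveform must be display-filtered first", call. = FALSE)
  }
}

#' Annotate an ABR waveform
#'
#' Resolves the Jewett peaks on a filtered ABR waveform: peak I first
#' (interval rule only), then peak III constrained by the I-III interpeak
#' gap, then peak V constrained by the III-V and I-V gaps (constraints whose
#' anchor was not found are skipped). Peaks II and IV are then resolved as
#' assisting waves strictly between their found neighbours; their absence
#' never invalidates I, III or V. Any wave with no qualifying candidate is
#' `NA`.
#'
#' @param w A filtered ABR `aep_waveform`.
#' @param ex The `extrema_set` computed from `w`.
#' @param cfg An ABR [rule_config()].
#' @return An `aep_annotation` with entries `I, II, III, IV, V`.
#' @export
annotate_abr <- function(w, ex, cfg = default_rule_config("ABR")) {
  check_annotation_input(w, "ABR")
  stopifnot(inherits(ex, "extrema_set"), cfg$subtype == "ABR")
  found <- list()
  lat_of <- function(lbl) {
    if (is.null(found[[lbl]]) || is.na(found[[lbl]])) NA_real_
    else w$times_ms[found[[lbl]]]
  }
  gap_cons <- function(from, to) {
    a <- lat_of(from)
    if (is.na(a)) return(NULL)
    anchor_constraint(a, gap_rule_for(cfg, from, to), "after")
  }
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

  found$I <- select_wave(ex, w, cfg$interval_rules$I, list(), cfg)
  found$III <- select_wave(ex, w, cfg$interval_rules$III,
                           drop_null(list(gap_cons("I", "III"))), cfg)
  found$V <- select_wave(ex, w, cfg$interval_rules$V,
                         drop_null(list(gap_cons("III", "V"),
                                        gap_cons("I", "V"))), cfg)
  # assisting waves, strictly between their neighbours when those are found
  between <- function(lo_lbl, hi_lbl) {
    lo <- lat_of(lo_lbl); hi <- lat_of(hi_lbl)
    bounds_constraint(if (is.na(lo)) -Inf else lo,
                      if (is.na(hi)) Inf else hi)
  }
  found$II <- select_wave(ex, w, cfg$interval_rules$II,
                          list(between("I", "III")), cfg)
  found$IV <- select_wave(ex, w, cfg$interval_rules$IV,
                          list(between("III", "V")), cfg)

  waves <- lapply(stats::setNames(nm = subtype_waves("ABR")), function(lbl) {
    i <- found[[lbl]]
    if (is.na(i)) wave_na() else wave_at(w, i)
  })
  enforce_canonical_order(new_annotation("ABR", waves, w$source_id),
                          assisting = c("II", "IV"))
}

#' Annotate an AMLR waveform
#'
#' Resolves the middle-latency components on a filtered AMLR waveform,
#' starting from the basal Pa peak, chosen by maximum amplitude within its
#' latency intervals. If Pa is not found the whole annotation is `NA`.
#' Otherwise Na is the qualifying trough before Pa (Na-Pa gap inside its
#' allowed window), Nb the trough after Pa ranked by time distance (gap
#' closest to the midpoint of the allowed Pa-Nb window; amplitude only
#' breaks ties), and Pb the peak after Nb ranked the same way against the
#' Nb-Pb window, falling back to a Pa-Pb window when Nb is `NA`.
#'
#' @param w A filtered AMLR `aep_waveform`.
#' @param ex The `extrema_set` computed from `w`.
#' @param cfg An AMLR [rule_config()].
#' @return An `aep_annotation` with entries `Na, Pa, Nb, Pb`.
#' @export
annotate_amlr <- function(w, ex, cfg = default_rule_config("AMLR")) {
  check_annotation_input(w, "AMLR")
  stopifnot(inherits(ex, "extrema_set"), cfg$subtype == "AMLR")
  waves <- lapply(stats::setNames(nm = subtype_waves("AMLR")),
                  function(lbl) wave_na())

  pa <- select_wave(ex, w, cfg$interval_rules$Pa, list(), cfg)
  if (is.na(pa)) {
    return(new_annotation("AMLR", waves, w$source_id))
  }
  waves$Pa <- wave_at(w, pa)
  pa_ms <- waves$Pa$latency_ms

  na_con <- anchor_constraint(pa_ms, gap_rule_for(cfg, "Na", "Pa"), "before")
  na <- select_wave(ex, w, cfg$interval_rules$Na, list(na_con), cfg)
  if (!is.na(na)) waves$Na <- wave_at(w, na)

  nb_con <- anchor_constraint(pa_ms, gap_rule_for(cfg, "Pa", "Nb"), "after")
  nb <- select_wave(ex, w, cfg$interval_rules$Nb, list(nb_con), cfg,
                    mode = "time", time_anchor = nb_con)
  if (!is.na(nb)) waves$Nb <- wave_at(w, nb)

  pb_con <- if (!is.na(nb)) {
    anchor_constraint(w$times_ms[nb], gap_rule_for(cfg, "Nb", "Pb"), "after")
  } else {
    anchor_constraint(pa_ms, gap_rule_for(cfg, "Pa", "Pb"), "after")
  }
  pb <- select_wave(ex, w, cfg$interval_rules$Pb, list(pb_con), cfg,
                    mode = "time", time_anchor = pb_con)
  if (!is.na(pb)) waves$Pb <- wave_at(w, pb)

  new_annotation("AMLR", waves, w$source_id)
}

# Drop assisting waves that break the canonical latency order; primary waves
# are never dropped (their pairwise gaps are already rule-constrained).
enforce_canonical_order <- function(ann, assisting = character()) {
  labels <- names(ann$waves)
  repeat {
    lats <- vapply(ann$waves, function(wv) wv$latency_ms, numeric(1))
    present <- labels[!is.na(lats)]
    ok <- !is.unsorted(lats[present], strictly = TRUE)
    if (ok || !length(intersect(present, assisting))) break
    # drop an assisting wave whose removal restores order, else the first
    drop <- intersect(present, assisting)[1L]
    for (lbl in intersect(present, assisting)) {
      lats2 <- lats[setdiff(present, lbl)]
      if (!is.unsorted(lats2, strictly = TRUE)) { drop <- lbl; break }
    }
    ann$waves[[drop]] <- wave_na()
  }
  ann
}

#' Run the full annotation pipeline on one recording
#'
#' Convenience wrapper: [average_buffers()], [apply_display_filters()],
#' [find_local_extrema()] and the subtype's annotator, using the settings
#' carried by `cfg`.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [rule_config()] for `rec$subtype` (defaults to
#'   [default_rule_config()]).
#' @return A list with `annotation`, `waveform` (filtered), and `extrema`.
#' @export
annotate_recording <- function(rec, cfg = default_rule_config(rec$subtype)) {
  stopifnot(cfg$subtype == rec$subtype)
  w <- apply_display_filters(average_buffers(rec), cfg$filter)
  ex <- find_local_extrema(w, cfg$extrema_window)
  ann <- if (rec$subtype == "ABR") annotate_abr(w, ex, cfg)
         else annotate_amlr(w, ex, cfg)
  list(annotation = ann, waveform = w, extrema = ex)
}
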