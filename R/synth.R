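# Synthetic AEP generator
# -----------------------
# Emulates the 450-sample epochs of the acquisition system: a clean template
# built as a sum of Gaussian-shaped wave components (negative amplitudes for
# troughs), two buffers formed by adding independent Gaussian noise draws to
# the template, and optional PAM spikes. Ground-truth wave positions are the
# template's own extrema, so every downstream stage can be scored without
# clinical data. Component widths, amplitudes and noise levels default to
# sub-microvolt magnitudes on the scale of real evoked responses.

SYNTH_RAW_SCALE <- 0.01 # raw unit = 10 nV; exercises the unit conversion

#' Synthesis parameters for one recording
#'
#' @param subtype `"ABR"` or `"AMLR"`.
#' @param components Data frame with columns `wave`, `latency_ms`,
#'   `amplitude_uv` (negative for troughs) and `width_ms` (Gaussian sigma);
#'   defaults to a typical morphology for the subtype.
#' @param buffer_noise_sd_uv Standard deviation of the independent Gaussian
#'   noise added to each buffer, in microvolts.
#' @param pam_spike Optional list `list(latency_ms=, amplitude_uv=,
#'   width_ms=)` describing a post-auricular-muscle spike added to the
#'   template (AMLR only).
#' @param seed Optional integer seed making the noise draws reproducible.
#' @return A `synth_params` object.
#' @export
synth_params <- function(subtype,
                         components = default_components(subtype),
                         buffer_noise_sd_uv = default_noise_sd(subtype),
                         pam_spike = NULL, seed = NULL) {
  subtype <- match.arg(subtype, SUBTYPES)
  stopifnot(is.data.frame(components),
            all(c("wave", "latency_ms", "amplitude_uv", "width_ms") %in%
                  names(components)),
            all(components$width_ms > 0),
            buffer_noise_sd_uv >= 0)
  win <- subtype_window_ms(subtype)
  if (any(components$latency_ms <= 0 | components$latency_ms >= win)) {
    stop("synth_params: component latencies must lie inside the analysis window",
         call. = FALSE)
  }
  structure(
    list(subtype = subtype, components = components,
         buffer_noise_sd_uv = buffer_noise_sd_uv,
         pam_spike = pam_spike, seed = seed),
    class = "synth_params"
  )
}

#' Typical component tables and noise levels
#'
#' ABR peaks I-V at their normative centres with sigma 0.25 ms and
#' 0.2-0.5 uV amplitudes; AMLR Na/Pa/Nb/Pb at mid-range latencies with
#' sigma 3 ms, Pa the largest component.
#'
#' @param subtype `"ABR"` or `"AMLR"`.
#' @return `default_components()`: a components data frame;
#'   `default_noise_sd()`: per-buffer noise sd in microvolts.
#' @export
default_components <- function(subtype) {
  switch(match.arg(subtype, SUBTYPES),
    ABR = data.frame(
      wave = c("I", "II", "III", "IV", "V"),
      latency_ms = c(1.5, 2.5, 3.5, 4.5, 5.5),
      amplitude_uv = c(0.30, 0.20, 0.35, 0.20, 0.45),
      width_ms = 0.25,
      stringsAsFactors = FALSE
    ),
    AMLR = data.frame(
      wave = c("Na", "Pa", "Nb", "Pb"),
      latency_ms = c(20, 30, 42, 60),
      amplitude_uv = c(-0.45, 1.1, -0.45, 0.5),
      width_ms = 3,
      stringsAsFactors = FALSE
    )
  )
}

#' @rdname default_components
#' @export
default_noise_sd <- function(subtype) {
  switch(match.arg(subtype, SUBTYPES), ABR = 0.05, AMLR = 0.1)
}

gaussian_bump <- function(t_ms, latency_ms, amplitude, width_ms) {
  amplitude * exp(-((t_ms - latency_ms)^2) / (2 * width_ms^2))
}

synth_template <- function(p, include_pam = TRUE) {
  t_ms <- build_time_axis(EPOCH_SAMPLES, subtype_sample_rate(p$subtype))
  template <- numeric(EPOCH_SAMPLES)
  for (i in seq_len(nrow(p$components))) {
    cmp <- p$components[i, ]
    template <- template +
      gaussian_bump(t_ms, cmp$latency_ms, cmp$amplitude_uv, cmp$width_ms)
  }
  if (include_pam && !is.null(p$pam_spike)) {
    template <- template +
      gaussian_bump(t_ms, p$pam_spike$latency_ms, p$pam_spike$amplitude_uv,
                    p$pam_spike$width_ms)
  }
  list(t_ms = t_ms, template = template)
}

# Ground truth: per component, the local extremum of the DISPLAY-FILTERED
# clean template (without artifact spikes) nearest the component centre,
# searched within +/- 3 sigma. Clinicians place their marks on the
# display-filtered waveform, so the synthetic "clinician" does the same;
# filtering shifts extrema slightly relative to the raw component centres
# (most visibly for AMLR troughs next to the large Pa). A component whose
# extremum does not survive display filtering -- neighbours merged it away,
# as happens for real assisting waves -- is absent from the gold mapping.
template_gold <- function(p, spec = default_filter_spec(p$subtype),
                          extrema_window = 4L) {
  tpl <- synth_template(p, include_pam = FALSE)
  wf <- new_waveform(p$subtype, tpl$template, subtype_sample_rate(p$subtype),
                     filtered = FALSE)
  filtered <- apply_display_filters(wf, spec)
  ex <- find_local_extrema(filtered, extrema_window)
  gold <- integer(nrow(p$components))
  merged <- character(0)
  for (i in seq_len(nrow(p$components))) {
    cmp <- p$components[i, ]
    win <- which(abs(tpl$t_ms - cmp$latency_ms) <= 3 * cmp$width_ms)
    loc <- intersect(if (cmp$amplitude_uv >= 0) ex$peaks else ex$troughs,
                     win)
    if (length(loc)) {
      gold[i] <- loc[which.min(abs(tpl$t_ms[loc] - cmp$latency_ms))]
    } else {
      merged <- c(merged, cmp$wave)
      gold[i] <- NA_integer_
    }
  }
  names(gold) <- p$components$wave
  # two components may fall onto one merged extremum; it belongs to the
  # component whose centre is nearer, the other wave is absent
  for (s in unique(gold[!is.na(gold)])) {
    claimants <- which(!is.na(gold) & gold == s)
    if (length(claimants) > 1L) {
      dist <- abs(tpl$t_ms[s] - p$components$latency_ms[claimants])
      lose <- claimants[-which.min(dist)]
      merged <- c(merged, p$components$wave[lose])
      gold[lose] <- NA_integer_
    }
  }
  gold <- gold[!is.na(gold)]
  attr(gold, "merged") <- merged
  gold
}

#' Generate one synthetic recording
#'
#' Builds the clean Gaussian-component template on the subtype's 450-sample
#' axis, draws two independent noise realisations for the buffers, and
#' packages the result as a [raw_recording()] whose `gold_waves` are the
#' extrema of the display-filtered clean template -- the positions an
#' ideal annotator of the clinician's filtered display would mark. The raw
#' buffers are stored in raw units so that averaging and microvolt
#' conversion through [average_buffers()] recover the simulated signal.
#'
#' @param p A [synth_params()].
#' @param patient_id,ear,stimulus_intensity Metadata stamped on the
#'   recording.
#' @return A [raw_recording()] with `gold_waves` set. Components whose
#'   extremum is merged away by a close neighbour after filtering are
#'   absent from `gold_waves` (as real assisting waves often are) and named
#'   in a `merged_waves` attribute.
#' @export
generate_recording <- function(p, patient_id = "synthetic", ear = "unknown",
                               stimulus_intensity = NA_real_) {
  stopifnot(inherits(p, "synth_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  tpl <- synth_template(p, include_pam = TRUE)
  gold <- template_gold(p)
  noise_a <- rnorm(EPOCH_SAMPLES, 0, p$buffer_noise_sd_uv)
  noise_b <- rnorm(EPOCH_SAMPLES, 0, p$buffer_noise_sd_uv)
  rec <- raw_recording(
    subtype = p$subtype,
    buffer_a = (tpl$template + noise_a) / SYNTH_RAW_SCALE,
    buffer_b = (tpl$template + noise_b) / SYNTH_RAW_SCALE,
    sample_rate = subtype_sample_rate(p$subtype),
    prestimulus_samples = 0L,
    raw_to_microvolt = SYNTH_RAW_SCALE,
    stimulus_intensity = stimulus_intensity,
    ear = ear,
    patient_id = patient_id,
    gold_waves = gold
  )
  if (length(attr(gold, "merged"))) {
    attr(rec, "merged_waves") <- attr(gold, "merged")
  }
  rec
}

# Per-wave latency and amplitude ranges used by the benchmark generator.
# Latencies are drawn uniformly inside the annotation rules' core intervals;
# amplitudes keep peak V / Pa the largest component of their subtype.
benchmark_ranges <- function(subtype, cfg = default_rule_config(subtype)) {
  amp <- switch(subtype,
    ABR = list(I = c(0.25, 0.35), II = c(0.15, 0.25), III = c(0.30, 0.40),
               IV = c(0.15, 0.25), V = c(0.40, 0.55)),
    AMLR = list(Na = c(-0.60, -0.30), Pa = c(0.80, 1.50),
                Nb = c(-0.60, -0.30), Pb = c(0.30, 0.70))
  )
  list(
    latency = lapply(cfg$interval_rules, function(r) r$core_ms),
    amplitude = amp,
    width_ms = switch(subtype, ABR = 0.25, AMLR = 3),
    min_separation_ms = switch(subtype, ABR = 0.6, AMLR = 6)
  )
}

draw_latencies <- function(subtype, ranges, cfg, max_tries = 1000L) {
  waves <- subtype_waves(subtype)
  for (try in seq_len(max_tries)) {
    lat <- vapply(waves, function(lbl) {
      r <- ranges$latency[[lbl]]
      runif(1, r[1], r[2])
    }, numeric(1))
    if (is.unsorted(lat, strictly = TRUE)) next
    if (any(diff(lat) < ranges$min_separation_ms)) next
    ok <- TRUE
    for (g in cfg$inter_wave_rules) {
      gap <- lat[[g$to_label]] - lat[[g$from_label]]
      if (gap < g$allowed_gap_ms[1] || gap > g$allowed_gap_ms[2]) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(lat)
  }
  stop(sprintf(
    "draw_latencies: no feasible %s latency draw in %d tries; constraints too tight",
    subtype, max_tries
  ), call. = FALSE)
}

#' Generate an annotated synthetic benchmark
#'
#' Draws `n` recordings with component latencies uniform inside the
#' configured core intervals (rejection-sampled to respect the inter-wave
#' gap rules and a minimum component separation), amplitudes uniform in
#' per-wave ranges with peak V / Pa the largest of their subtype, fixed
#' Gaussian widths, and independent buffer noise. A fraction of AMLR
#' recordings can be contaminated with a PAM spike (latency uniform in the
#' PAM window, amplitude a multiple of the recording's Pa amplitude);
#' ground-truth wave positions always refer to the artifact-free template.
#'
#' @param n Number of recordings (`>= 1`).
#' @param subtype `"ABR"` or `"AMLR"`.
#' @param seed Integer seed for all draws.
#' @param pam_fraction Fraction of recordings receiving a PAM spike
#'   (AMLR only; default 0).
#' @param cfg [rule_config()] whose intervals and gap rules define the
#'   sampling space.
#' @param noise_sd_uv Per-buffer noise sd; defaults to the subtype's
#'   standard level.
#' @param dir Optional directory: when given, each recording is written as
#'   an XML fixture (`rec_0001.xml`, ...) plus a `gold.csv` table.
#' @return List with `recordings` (list of [raw_recording()]), `gold`
#'   (data frame: id, wave, sample, latency_ms, amplitude_uv), and
#'   `pam_ids` (ids of spike-contaminated recordings).
#' @export
generate_benchmark <- function(n, subtype, seed = 42L, pam_fraction = 0,
                               cfg = default_rule_config(subtype),
                               noise_sd_uv = default_noise_sd(subtype),
                               dir = NULL) {
  if (n < 1) stop("generate_benchmark: n must be >= 1", call. = FALSE)
  subtype <- match.arg(subtype, SUBTYPES)
  stopifnot(pam_fraction >= 0, pam_fraction <= 1)
  set.seed(seed)
  ranges <- benchmark_ranges(subtype, cfg)
  waves <- subtype_waves(subtype)
  n_pam <- round(pam_fraction * n)
  pam_which <- if (n_pam > 0) sort(sample.int(n, n_pam)) else integer(0)

  recordings <- vector("list", n)
  gold_rows <- vector("list", n)
  ids <- sprintf("rec_%04d", seq_len(n))
  for (i in seq_len(n)) {
    lat <- draw_latencies(subtype, ranges, cfg)
    amp <- vapply(waves, function(lbl) {
      r <- ranges$amplitude[[lbl]]
      runif(1, r[1], r[2])
    }, numeric(1))
    comp <- data.frame(wave = waves, latency_ms = unname(lat),
                       amplitude_uv = unname(amp),
                       width_ms = ranges$width_ms, stringsAsFactors = FALSE)
    spike <- NULL
    if (i %in% pam_which) {
      spike <- list(latency_ms = runif(1, cfg$pam_window_ms[1],
                                       cfg$pam_window_ms[2]),
                    amplitude_uv = runif(1, 3, 5) * amp[["Pa"]],
                    width_ms = 2)
    }
    p <- synth_params(subtype, comp, noise_sd_uv, pam_spike = spike)
    rec <- generate_recording(p, patient_id = ids[i],
                              ear = sample(c("left", "right"), 1),
                              stimulus_intensity = if (subtype == "ABR")
                                sample(c(80, 90), 1) else 70)
    recordings[[i]] <- rec
    gw <- rec$gold_waves
    gold_rows[[i]] <- data.frame(
      id = ids[i], wave = names(gw), sample = as.integer(gw),
      latency_ms = build_time_axis(EPOCH_SAMPLES,
                                   subtype_sample_rate(subtype))[gw],
      amplitude_uv = comp$amplitude_uv[match(names(gw), comp$wave)],
      stringsAsFactors = FALSE
    )
  }
  gold <- do.call(rbind, gold_rows)
  names(recordings) <- ids

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      write_recording_xml(recordings[[i]], file.path(dir,
                                                     paste0(ids[i], ".xml")))
    }
    write.csv(gold, file.path(dir, "gold.csv"), row.names = FALSE)
  }
  list(recordings = recordings, gold = gold, pam_ids = ids[pam_which])
}
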