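# Fixture builders shared by the test files. Everything is generated in
# code; no stored data files.

# waveform constructed directly from amplitudes, optionally marked filtered
# so the rule engine can be tested in isolation from the filter stages
make_waveform <- function(subtype, amplitudes, filtered = TRUE,
                          source_id = "test") {
  structure(
    list(
      subtype = subtype,
      amplitudes = as.numeric(amplitudes),
      times_ms = build_time_axis(length(amplitudes),
                                 switch(subtype, ABR = 30000, AMLR = 3000)),
      sample_rate = switch(subtype, ABR = 30000, AMLR = 3000),
      filtered = filtered,
      source_id = source_id
    ),
    class = "aep_waveform"
  )
}

# sum of Gaussian bumps on the subtype's 450-sample axis
make_bump_signal <- function(subtype, latency_ms, amplitude_uv, width_ms) {
  t_ms <- build_time_axis(450, switch(subtype, ABR = 30000, AMLR = 3000))
  x <- numeric(450)
  for (i in seq_along(latency_ms)) {
    x <- x + amplitude_uv[i] *
      exp(-((t_ms - latency_ms[i])^2) / (2 * width_ms[i]^2))
  }
  x
}

# bare annotation object holding given sample indices (NA allowed)
make_annotation <- function(subtype, indices, source_id = "test") {
  labels <- switch(subtype,
                   ABR = c("I", "II", "III", "IV", "V"),
                   AMLR = c("Na", "Pa", "Nb", "Pb"))
  rate <- switch(subtype, ABR = 30000, AMLR = 3000)
  waves <- lapply(stats::setNames(nm = labels), function(lbl) {
    idx <- if (lbl %in% names(indices)) indices[[lbl]] else NA_integer_
    if (is.na(idx)) {
      list(index = NA_integer_, latency_ms = NA_real_,
           amplitude_uv = NA_real_)
    } else {
      list(index = as.integer(idx), latency_ms = 1000 * (idx - 1) / rate,
           amplitude_uv = 0.3)
    }
  })
  structure(list(subtype = subtype, waves = waves, source_id = source_id),
            class = "aep_annotation")
}

annotation_indices <- function(ann) {
  vapply(ann$waves, function(w) w$index, integer(1))
}

# independent brute-force oracle for the windowed extremum definition:
# plain double loop, truncated windows, strict-neighbour and
# earliest-of-plateau rules spelled out
oracle_windowed_peaks <- function(x, m) {
  n <- length(x)
  out <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1, i - m)
    hi <- min(n, i + m)
    ok <- TRUE
    for (j in lo:hi) if (x[j] > x[i]) { ok <- FALSE; break }
    if (!ok) next
    earlier_tie <- FALSE
    if (i > lo) for (j in lo:(i - 1)) if (x[j] == x[i]) earlier_tie <- TRUE
    if (earlier_tie) next
    strict <- FALSE
    if (i > 1 && x[i - 1] < x[i]) strict <- TRUE
    if (i < n && x[i + 1] < x[i]) strict <- TRUE
    if (strict) out <- c(out, i)
  }
  out
}
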