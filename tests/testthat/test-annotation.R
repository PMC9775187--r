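abr_cfg <- default_rule_config("ABR")
amlr_cfg <- default_rule_config("AMLR")

test_that("core candidates beat expanded ones unless much larger", {
  # wave I: core 1-2 ms, expanded 0.5-2.5 ms; bump at 1.5 ms is core,
  # bump at 2.3 ms expanded-only
  run_case <- function(core_amp, exp_amp) {
    x <- make_bump_signal("ABR", c(1.5, 2.3), c(core_amp, exp_amp),
                          c(0.15, 0.15))
    w <- make_waveform("ABR", x)
    ex <- find_local_extrema(w, 4)
    idx <- select_wave(ex, w, abr_cfg$interval_rules$I, list(), abr_cfg)
    w$times_ms[idx]
  }
  expect_equal(run_case(0.30, 0.36), 1.5, tolerance = 0.05) # 0.36 < 1.5*0.30
  expect_equal(run_case(0.30, 0.70), 2.3, tolerance = 0.05) # 0.70 >= 0.45
})

test_that("select_wave returns NA when no candidate is in the window", {
  w <- make_waveform("ABR", make_bump_signal("ABR", 9, 0.4, 0.2))
  ex <- find_local_extrema(w, 4)
  expect_identical(select_wave(ex, w, abr_cfg$interval_rules$I, list(),
                               abr_cfg),
                   NA_integer_)
})

test_that("clean ABR peaks at the normative centres are recovered", {
  p <- synth_params("ABR", buffer_noise_sd_uv = 0)
  rec <- generate_recording(p)
  ann <- annotate_recording(rec)$annotation
  lat <- vapply(ann$waves, function(wv) wv$latency_ms, numeric(1))
  step <- 1000 / 30000
  expect_lte(abs(lat[["I"]] - 1.5), step + 1e-9)
  expect_lte(abs(lat[["III"]] - 3.5), step + 1e-9)
  expect_lte(abs(lat[["V"]] - 5.5), step + 1e-9)
})

test_that("flat waveforms annotate as all NA in both subtypes", {
  for (subtype in c("ABR", "AMLR")) {
    w <- make_waveform(subtype, rep(0, 450))
    ex <- find_local_extrema(w, 4)
    ann <- if (subtype == "ABR") annotate_abr(w, ex, abr_cfg)
           else annotate_amlr(w, ex, amlr_cfg)
    expect_true(all(is.na(annotation_indices(ann))))
  }
})

test_that("a lone late candidate beyond the peak V cap is rejected", {
  w <- make_waveform("ABR", make_bump_signal("ABR", 7.5, 0.5, 0.2))
  ex <- find_local_extrema(w, 4)
  ann <- annotate_abr(w, ex, abr_cfg)
  expect_true(is.na(ann$waves$V$index))
  # even an explicitly widened expanded range cannot pass the 7 ms cap
  wide <- abr_cfg
  wide$interval_rules$V <- wave_interval_rule("V", "peak", c(5, 6), c(4.5, 8),
                                              hard_cap_ms = 7)
  expect_true(is.na(annotate_abr(w, ex, wide)$waves$V$index))
})

test_that("clean AMLR components at typical latencies are recovered", {
  comp <- data.frame(wave = c("Na", "Pa", "Nb", "Pb"),
                     latency_ms = c(20, 30, 40, 60),
                     amplitude_uv = c(-0.5, 1.2, -0.5, 0.5),
                     width_ms = 3, stringsAsFactors = FALSE)
  p <- synth_params("AMLR", components = comp, buffer_noise_sd_uv = 0)
  rec <- generate_recording(p)
  ann <- annotate_recording(rec)$annotation
  idx <- annotation_indices(ann)
  expect_false(anyNA(idx))
  expect_true(all(abs(idx - rec$gold_waves[names(idx)]) <= 1))
})

test_that("Pa is picked inside its interval, not an earlier larger peak", {
  # large peak near 15 ms lies outside the Pa window; the true Pa near
  # 27 ms must win despite its smaller amplitude
  x <- make_bump_signal("AMLR", c(15, 27), c(1.5, 0.8), c(3, 3))
  w <- make_waveform("AMLR", x)
  ex <- find_local_extrema(w, 4)
  ann <- annotate_amlr(w, ex, amlr_cfg)
  expect_equal(ann$waves$Pa$latency_ms, 27, tolerance = 0.5)
})

test_that("when Pa is absent the whole AMLR annotation is NA", {
  # only an early bump: no Pa candidate anywhere in its expanded range
  x <- make_bump_signal("AMLR", 15, 1.0, 2)
  w <- make_waveform("AMLR", x)
  ex <- find_local_extrema(w, 4)
  ann <- annotate_amlr(w, ex, amlr_cfg)
  expect_true(all(is.na(annotation_indices(ann))))
})

test_that("annotators demand a filtered waveform of the right subtype", {
  w_raw <- make_waveform("ABR", rnorm(450), filtered = FALSE)
  ex <- find_local_extrema(w_raw, 4)
  expect_error(annotate_abr(w_raw, ex, abr_cfg), "filtered")
  w_amlr <- make_waveform("AMLR", rnorm(450))
  expect_error(annotate_abr(w_amlr, find_local_extrema(w_amlr, 4), abr_cfg),
               "expected a ABR")
})

test_that("annotations are ordered, extrema members, and deterministic", {
  for (subtype in c("ABR", "AMLR")) {
    b <- generate_benchmark(25, subtype, seed = 91)
    for (rec in b$recordings) {
      res <- annotate_recording(rec)
      idx <- annotation_indices(res$annotation)
      present <- idx[!is.na(idx)]
      # canonical order, strictly increasing
      expect_false(is.unsorted(present, strictly = TRUE))
      # polarity-correct membership in the candidate set
      for (lbl in names(present)) {
        pol <- if (subtype == "ABR" || lbl %in% c("Pa", "Pb")) "peaks"
               else "troughs"
        expect_true(present[[lbl]] %in% res$extrema[[pol]])
      }
      # determinism: a second run reproduces the annotation exactly
      expect_identical(idx, annotation_indices(
        annotate_recording(rec)$annotation
      ))
    }
  }
})

test_that("noise-free recordings are recovered wave-for-wave within 1 sample", {
  for (subtype in c("ABR", "AMLR")) {
    b <- generate_benchmark(100, subtype, seed = 11, noise_sd_uv = 0)
    n_checked <- 0L
    for (rec in b$recordings) {
      ann <- annotate_recording(rec)$annotation
      idx <- annotation_indices(ann)[names(rec$gold_waves)]
      expect_false(anyNA(idx))
      expect_true(all(abs(idx - rec$gold_waves) <= 1))
      n_checked <- n_checked + length(idx)
    }
    expect_gte(n_checked, 300)
  }
})
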