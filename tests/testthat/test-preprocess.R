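test_that("buffer averaging is the scaled elementwise mean", {
  mk <- function(a, b, scale) {
    raw_recording("ABR", a, b, 30000, raw_to_microvolt = scale)
  }
  x <- sin(seq_len(450))
  expect_equal(average_buffers(mk(x, x, 1))$amplitudes, x)
  expect_equal(average_buffers(mk(x, -x, 1))$amplitudes, rep(0, 450))
  w <- average_buffers(mk(c(1, 3, rep(0, 448)), c(3, 5, rep(0, 448)), 0.5))
  expect_equal(w$amplitudes[1:2], c(1.0, 2.0))
  expect_false(w$filtered)
})

test_that("buffer averaging is linear in the buffers", {
  set.seed(21)
  a <- rnorm(450); b <- rnorm(450)
  for (alpha in c(-2, 0.3, 7)) {
    w1 <- average_buffers(raw_recording("AMLR", alpha * a, alpha * b, 3000,
                                        raw_to_microvolt = 0.4))
    w0 <- average_buffers(raw_recording("AMLR", a, b, 3000,
                                        raw_to_microvolt = 0.4))
    expect_equal(w1$amplitudes, alpha * w0$amplitudes, tolerance = 1e-12)
  }
})

test_that("the stimulus-locked axis starts at 0 and spans the analysis window", {
  t_abr <- build_time_axis(450, 30000)
  expect_identical(t_abr[1], 0)
  expect_equal(diff(t_abr), rep(1 / 30, 449), tolerance = 1e-12)
  expect_equal(t_abr[450], 449 / 30)          # just under the 15 ms window
  t_amlr <- build_time_axis(450, 3000)
  expect_equal(t_amlr[450], 4490 / 30)        # just under 150 ms
  expect_identical(build_time_axis(1, 30000), 0)
})

test_that("DC is rejected by the display high-pass", {
  for (subtype in c("ABR", "AMLR")) {
    w <- make_waveform(subtype, rep(2.5, 450), filtered = FALSE)
    out <- apply_display_filters(w, default_filter_spec(subtype))
    expect_lt(max(abs(out$amplitudes)), 1e-6 * 2.5)
    expect_true(out$filtered)
    expect_identical(out$times_ms, w$times_ms)
    expect_length(out$amplitudes, 450)
  }
})

# independent oracle: evaluate the designed transfer functions at f;
# forward-backward application squares each stage's magnitude
filter_gain_oracle <- function(spec, fs, f) {
  nyq <- fs / 2
  b_lp <- as.numeric(signal::fir1(spec$fir_order, spec$low_pass_hz / nyq))
  hp <- signal::butter(spec$butter_order, spec$high_pass_hz / nyq,
                       type = "high")
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(b_lp) - 1))
  h_lp <- abs(sum(b_lp * z))
  zb <- exp(-1i * 2 * pi * f / fs * (seq_along(hp$b) - 1))
  za <- exp(-1i * 2 * pi * f / fs * (seq_along(hp$a) - 1))
  h_hp <- abs(sum(hp$b * zb) / sum(hp$a * za))
  (h_lp * h_hp)^2
}

test_that("the AMLR passband preserves a 50 Hz tone and crushes 500 Hz", {
  spec <- default_filter_spec("AMLR")
  t <- build_time_axis(450, 3000) / 1000
  rms <- function(x) sqrt(mean(x^2))
  mid <- 100:350   # away from the record edges

  tone50 <- make_waveform("AMLR", sin(2 * pi * 50 * t), filtered = FALSE)
  out50 <- apply_display_filters(tone50, spec)
  gain50 <- rms(out50$amplitudes[mid]) / rms(tone50$amplitudes[mid])
  expect_gt(gain50, 0.9)
  expect_lt(gain50, 1.1)
  expect_equal(gain50, filter_gain_oracle(spec, 3000, 50), tolerance = 0.03)

  tone500 <- make_waveform("AMLR", sin(2 * pi * 500 * t), filtered = FALSE)
  out500 <- apply_display_filters(tone500, spec)
  gain500 <- rms(out500$amplitudes[mid]) / rms(tone500$amplitudes[mid])
  expect_lt(gain500, 10^(-20 / 20))
  expect_lt(filter_gain_oracle(spec, 3000, 500), 10^(-20 / 20))
})

test_that("zero-phase filtering moves a clean bump's argmax by at most 1 sample", {
  cases <- list(list(subtype = "ABR", lat = 3.5, width = 0.25),
                list(subtype = "AMLR", lat = 30, width = 3))
  for (cs in cases) {
    x <- make_bump_signal(cs$subtype, cs$lat, 0.5, cs$width)
    w <- make_waveform(cs$subtype, x, filtered = FALSE)
    out <- apply_display_filters(w, default_filter_spec(cs$subtype))
    expect_lte(abs(which.max(out$amplitudes) - which.max(x)), 1)
  }
})

test_that("misconfigured filters are refused", {
  expect_error(display_filter_spec(100, 150), "low_pass_hz > high_pass_hz")
  w <- make_waveform("AMLR", rnorm(450), filtered = FALSE)
  expect_error(
    apply_display_filters(w, display_filter_spec(2000, 15)),
    "Nyquist"
  )
  filtered <- apply_display_filters(w)
  expect_error(apply_display_filters(filtered), "already filtered")
})
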