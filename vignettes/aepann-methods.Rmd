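---
title: "Annotating auditory evoked potentials: models, rules and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating auditory evoked potentials: models, rules and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aepann)
```

## Signal model

An auditory evoked potential is the average of thousands of stimulus-locked
sweeps; the acquisition system accumulates alternate sweeps into two
buffers, and the displayed waveform is their mean converted to microvolts.
Each exported epoch holds 450 samples. For the ABR the sampling rate is
30 kHz, so the epoch spans 15 ms; for the AMLR it is 3 kHz over 150 ms. The
system starts the stimulus early enough that the first stored sample
coincides with stimulus completion, so the time axis starts at 0 ms there
and any pre-stimulus samples are metadata only.

Averaging the two buffers halves the noise variance relative to a single
buffer (the `1/sqrt(2)` RMS reduction is verified by a Monte-Carlo test),
which is why the annotator always works on the averaged waveform.

## Display filtering

Clinicians do not annotate the raw average: they view it through visual
display filters. We reproduce that pipeline with a linear-phase FIR
low-pass (`signal::fir1`) and a Butterworth high-pass (`signal::butter`):
150–1500 Hz for ABR, 15–100 Hz for AMLR. Three numerical choices matter,
none of which is dictated by the band edges themselves:

* **Orders** (FIR 100, Butterworth 2 by default): conventional, stable
  choices; both are configurable because the hardware's own display
  filters are not public and any reimplementation is necessarily an
  approximation.
* **Zero-phase application**: both stages are run forward–backward
  (`signal::filtfilt`). Latency is the measured quantity, and causal
  filtering would bias every latency by the group delay. A causal mode is
  retained in the configuration for fidelity experiments; it compensates
  the FIR stage's known linear delay.
* **Edge handling**: the waveform is baseline-corrected (mean removed) and
  reflect-padded by the longer of one FIR length and eight high-pass time
  constants before filtering, then trimmed. Without this, the high-pass
  step transient at the record ends spawns spurious extrema precisely where
  expanded search windows can reach.

The high-pass visibly reshapes the slow AMLR waves: the undershoot of the
large Pa component pulls neighbouring troughs toward it by a few samples.
This is a property of the *display*, shared by what the clinician sees, and
is why ground truth in the synthetic benchmark is defined on the filtered
template (below).

## Candidate extrema

Sample `i` is a candidate peak if it is the maximum over `[i - m, i + m]`
(windows truncated at the record ends) and strictly exceeds at least one
immediate neighbour; exact ties collapse to the earliest sample of the
plateau; troughs are peaks of the negated signal. The half-window `m`
(default 4 samples, per-subtype configurable) suppresses single-sample
noise wiggles while keeping genuine physiological turning points; the
original tool's value is not published, and 4 samples matches the match
tolerance scale. Boundary samples stay eligible: the waves of interest
never occur there under default windows, but silently excluding them would
bias deliberately widened intervals. The implementation is checked against
a brute-force double-loop oracle on random signals.

## Selection rules

Each wave has a **core** (normal) latency interval and an **expanded**
interval enclosing it, plus inter-wave gap constraints. Among feasible
candidates, one in the core range with the most extreme amplitude wins
unless an expanded-only candidate is *much larger* — at least 1.5× by
default, judged in the wave's polarity direction (so a negative local
maximum on a flank can never displace a genuine small peak). Time-related
conditions always take priority over amplitude-related ones.

The ABR annotator resolves peak I, then III (constrained by the I–III
gap), then V (III–V and I–V gaps); constraints whose anchor was not found
are skipped, and a wave with no qualifying candidate is NA without blocking
the rest. Waves II and IV are assisting waves, searched afterwards strictly
between their neighbours; their absence never invalidates I, III or V. The
AMLR annotator starts from the basal Pa component (maximum amplitude within
its interval; Pa absent means the recording is unannotatable), then Na
before it, then Nb and Pb after it with **time-distance priority**: among
plausible candidates, the one whose gap to its anchor is closest to the
midpoint of the allowed gap window wins, amplitude only breaking ties.

Reconstructed defaults, all configuration rather than code:

* ABR core intervals: centres 1.5/2.5/3.5/4.5/5.5 ms ± 0.5 ms; expanded
  ± 1.0 ms; peak V hard-capped at 7.0 ms. Published normative centres give
  only the midpoints; the half-widths keep the primary cores disjoint,
  which the sequential search assumes.
* ABR gaps: I→III and III→V 2.0 ± 1.0 ms, I→V 4.0 ± 1.0 ms. The
  literature states the 2.0/4.0 ms expectations as points; ±1 ms makes
  them usable as constraints.
* AMLR cores: Na 18–25, Pa 24–36, Nb 34–47, Pb 55–80 ms (the published
  acceptable ranges); expanded ranges are the envelope of the conflicting
  normative sources (Na 12–30, Pa 21–45, Nb 34–56.26, Pb 46.25–90 ms).
* AMLR gaps: Na→Pa 7.50–18.75 ms as published; Pa→Nb, Nb→Pb and Pa→Pb are
  the gap ranges *implied* by the core interval tables (e.g. Nb→Pb spans
  `55−47` to `80−34` ms). An earlier round-number cap proved wrong: it made
  boundary-legal Pb positions infeasible.
* `min_rel_amplitude` (default 0.4): time-distance ranking considers only
  candidates within 40% of the largest feasible amplitude. Pure
  gap-midpoint ranking reliably selects low-amplitude noise ripples
  whenever the true gap is far from the window midpoint; the guard keeps
  the time-priority semantics while restricting it to physiologically
  plausible candidates. Setting it to 0 restores the unguarded rule.

These interval tables are reconstructions from published normative values,
not the (unpublished) final tuned values of any clinical deployment; the
YAML configuration file exists precisely so a site can re-tune them against
its own annotated data.

## PAM screening

The post-auricular-muscle reflex contaminates AMLR recordings as a sharp
spike at 13–15 ms — before Pa — much larger than Pa. The screen flags a
recording when any candidate extremum in that window has absolute amplitude
at least `pam_ratio` (default 2.0, "much larger" being unquantified in the
literature) times the annotated Pa amplitude; with Pa unannotated, the
largest absolute amplitude in the Pa core interval substitutes, and an
identically zero region falls back to the waveform RMS. Sharpness is not
tested separately: the narrow window plus the amplitude ratio is the
operational criterion, since no published width or slope threshold exists.
Detection is monotone in the ratio (raising it never creates a detection).

## Scoring

A wave is evaluable when the gold standard marks it, and matched when the
automated index deviates by at most ±4 samples (boundary inclusive):
4·15/450 ≈ 0.13 ms for ABR, 4·150/450 ≈ 1.33 ms for AMLR. Gold-NA waves
leave the denominator (rates then read as sensitivities on clinically
identifiable waves); a predicted NA against a marked wave is a miss. Both
choices are flags on `compute_match_rates()`, since conventions for
unmarked gold waves differ between studies. Mismatches are exported to a
review CSV by the `evaluate` command.

## The synthetic generator

Without redistributable clinical recordings, validation runs on synthetic
epochs: a clean template that is a sum of Gaussian components, plus
independent Gaussian noise per buffer.

* Widths: σ = 0.25 ms (ABR), 3 ms (AMLR) — narrow enough to keep
  neighbouring waves separable at the two sampling rates, wide enough to
  survive the display low-pass.
* Amplitudes: ABR 0.15–0.55 µV with peak V the largest (real responses are
  sub-microvolt); AMLR 0.3–1.5 µV with Pa the largest, troughs negative.
* Buffer noise: 0.05 µV (ABR) and 0.1 µV (AMLR) per buffer, giving
  realistic post-filter SNRs of roughly 10–20.
* Benchmarks draw latencies uniformly inside the core intervals, rejection
  sampled (cap 1000 tries) to respect the inter-wave gap rules and a
  minimum component separation of 0.6 ms (ABR) / 6 ms (AMLR), about 2.4σ
  and 2σ — closer components merge into one extremum even on the clean
  display.
* PAM spikes: Gaussian, σ = 2 ms, latency uniform in 13–15 ms, amplitude
  3–5× the recording's Pa. The width matters: the 100 Hz display low-pass
  attenuates a much sharper spike below the detection ratio, which would
  be unfaithful to the large artifact the screen is meant to catch.

**Ground truth** is the set of local extrema of the *display-filtered*
clean template nearest each component centre (deduplicated when two
components merge onto one extremum; a component whose extremum does not
survive filtering — typically ABR assisting waves II/IV at tight spacings —
is absent from the gold standard, as assisting waves often are in real
recordings). Defining truth on the filtered template mirrors the clinical
gold standard, which is placed on the filtered display; against the raw
template the display filter itself would contribute a systematic 2–6 sample
bias for AMLR troughs that no annotator of the displayed waveform could
avoid.

What the generator does **not** model: the acquisition filter chain,
non-Gaussian wave shapes, latency–intensity dependence, hearing-loss
morphology, inter-subject amplitude correlations, or "grey-zone" waveforms
on which human annotators disagree. Benchmark match rates on this generator
therefore validate the *rule engine and pipeline mechanics* — that the
right extremum is selected under noise wherever an identifiable extremum
exists — and are expected to exceed match rates attainable against human
annotations of clinical data.

## Validation setup

The shipped tests run the full pipeline on seeded benchmarks of 300
recordings per subtype with the default generator settings (a size chosen
to mirror the scale of the clinical validation sets while keeping the whole
suite fast), score them with the ±4-sample rule, and additionally verify:
exact recovery (deviation 0) on noise-free benchmarks; extrema equivalence
with a brute-force oracle; peak/trough duality; filter DC rejection and
passband gain against an analytic frequency-response oracle; match-rate
monotonicity in the tolerance; XML round-trip identity; and seeded
reproducibility. The PAM screen-drop-rescore protocol is verified on a
benchmark where spikes are the only corruption, where exclusion provably
cannot lower any per-wave rate; with buffer noise present, a wave untouched
by the artifact can lose a fraction of a percent simply because its rare
noise-driven misses sit in the retained recordings.

## Known limitations

* The interval tables are literature reconstructions; sites should re-tune
  them (the YAML config replaces the original's manual re-tuning loop).
* The display filters approximate, but cannot replicate, the proprietary
  implementation the clinicians viewed; on real exports small systematic
  latency differences are expected.
* Waves II and IV are annotated on a best-effort basis only.
* The PAM screen is a detector, not a corrector: flagged recordings are
  excluded, never repaired. Filter-settings artifacts are prevented by the
  configuration defaults rather than detected.
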