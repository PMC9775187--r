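Package: aepann
Title: Automated Annotation of Auditory Brainstem and Middle Latency Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs auditory evoked potential (AEP) waveforms from
    dual-buffer XML exports, applies the visual display filters clinicians
    use for interpretation, detects candidate peaks and troughs, and selects
    the clinically meaningful waves (ABR Jewett peaks I-V; AMLR components
    Na, Pa, Nb, Pb) with a rule engine built on normative latency intervals,
    inter-wave gaps and amplitude priorities. Includes screening for
    post-auricular-muscle (PAM) artifacts in middle latency recordings,
    scoring of automated annotations against clinician gold standards under
    a sample-deviation tolerance, and a synthetic-recording generator with
    ground-truth wave positions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
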