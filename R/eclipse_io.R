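# XML dialect for AEP recordings
# ------------------------------
# One <AEPRecording> element per file. Raw samples are whitespace-separated
# decimal text inside <IPSI_A_RAW> and <IPSI_B_RAW> (the two acquisition
# buffers). Clinician wave positions live under <Jewetts> as
# <Jewett Wave="V" Sample="165"/> with 0-based sample indices; R-side objects
# use 1-based indices and the reader/writer converts. A machine-readable
# sketch of the dialect ships in inst/extdata/aep-recording-dialect.md.

DIALECT_ROOT <- "AEPRecording"

#' Read an AEP recording from XML
#'
#' Parses one recording in the package's documented XML dialect: the two raw
#' acquisition buffers (`IPSI_A_RAW`, `IPSI_B_RAW`), sampling metadata
#' (`SampleRate`, `PrestimulusSamples`, `RawToMicrovolt`), stimulus metadata
#' (`Subtype`, `Intensity`, `Ear`, `PatientID`) and, when present, clinician
#' wave positions under `Jewetts`. Raw values are returned exactly as stored,
#' not yet averaged or scaled to microvolts.
#'
#' @param path Path to an XML file in the dialect.
#' @return A [raw_recording()].
#' @seealso [write_recording_xml()]
#' @export
read_recording_xml <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("recording file not found: %s", path), call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("malformed XML in %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  root <- xml2::xml_name(doc)
  if (!identical(root, DIALECT_ROOT)) {
    stop(sprintf("malformed XML in %s: root element is <%s>, expected <%s>",
                 path, root, DIALECT_ROOT), call. = FALSE)
  }

  field <- function(tag, required = TRUE) {
    node <- xml2::xml_find_first(doc, paste0("./", tag))
    if (inherits(node, "xml_missing")) {
      if (required) {
        stop(sprintf("missing element <%s> in %s", tag, path), call. = FALSE)
      }
      return(NA_character_)
    }
    xml2::xml_text(node)
  }
  parse_buffer <- function(tag) {
    node <- xml2::xml_find_first(doc, paste0("./", tag))
    if (inherits(node, "xml_missing")) {
      stop(sprintf("missing buffer element <%s> in %s", tag, path),
           call. = FALSE)
    }
    txt <- trimws(xml2::xml_text(node))
    vals <- suppressWarnings(as.numeric(strsplit(txt, "\\s+")[[1]]))
    if (length(vals) == 0L || anyNA(vals)) {
      stop(sprintf("non-numeric or empty sample data in <%s> of %s",
                   tag, path), call. = FALSE)
    }
    vals
  }

  buffer_a <- parse_buffer("IPSI_A_RAW")
  buffer_b <- parse_buffer("IPSI_B_RAW")
  if (length(buffer_a) != length(buffer_b)) {
    stop(sprintf(
      "inconsistent buffers in %s: IPSI_A_RAW has %d samples, IPSI_B_RAW has %d",
      path, length(buffer_a), length(buffer_b)
    ), call. = FALSE)
  }

  gold <- NULL
  jew <- xml2::xml_find_all(doc, "./Jewetts/Jewett")
  if (length(jew)) {
    lbl <- xml2::xml_attr(jew, "Wave")
    # dialect stores 0-based indices; R objects are 1-based
    idx <- as.integer(xml2::xml_attr(jew, "Sample")) + 1L
    if (anyNA(lbl) || anyNA(idx)) {
      stop(sprintf("malformed <Jewett> element in %s", path), call. = FALSE)
    }
    gold <- stats::setNames(idx, lbl)
  }

  intensity <- field("Intensity", required = FALSE)
  ear <- field("Ear", required = FALSE)
  raw_recording(
    subtype = field("Subtype"),
    buffer_a = buffer_a,
    buffer_b = buffer_b,
    sample_rate = as.numeric(field("SampleRate")),
    prestimulus_samples = as.integer(field("PrestimulusSamples")),
    raw_to_microvolt = as.numeric(field("RawToMicrovolt")),
    stimulus_intensity = suppressWarnings(as.numeric(intensity)),
    ear = if (is.na(ear)) "unknown" else ear,
    patient_id = {
      pid <- field("PatientID", required = FALSE)
      if (is.na(pid)) "" else pid
    },
    gold_waves = gold
  )
}

#' Write an AEP recording to XML
#'
#' Serializes a [raw_recording()] into the dialect read by
#' [read_recording_xml()]; the round trip reproduces every field (numeric
#' buffers to full double precision). Wave positions are written 0-based as
#' `<Jewett Wave=".." Sample=".."/>` elements.
#'
#' @param rec A valid [raw_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_xml <- function(rec, path) {
  validate_raw_recording(rec)
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  doc <- xml2::xml_new_root(DIALECT_ROOT)
  add <- function(tag, value) {
    xml2::xml_add_child(doc, tag, as.character(value))
  }
  add("Subtype", rec$subtype)
  add("PatientID", rec$patient_id)
  add("Ear", rec$ear)
  add("Intensity", if (is.na(rec$stimulus_intensity)) "" else
    num(rec$stimulus_intensity))
  add("SampleRate", num(rec$sample_rate))
  add("PrestimulusSamples", rec$prestimulus_samples)
  add("RawToMicrovolt", num(rec$raw_to_microvolt))
  add("IPSI_A_RAW", paste(num(rec$buffer_a), collapse = " "))
  add("IPSI_B_RAW", paste(num(rec$buffer_b), collapse = " "))
  if (!is.null(rec$gold_waves)) {
    jew <- xml2::xml_add_child(doc, "Jewetts")
    for (lbl in names(rec$gold_waves)) {
      xml2::xml_add_child(jew, "Jewett",
                          Wave = lbl,
                          Sample = as.character(rec$gold_waves[[lbl]] - 1L))
    }
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop(sprintf("cannot write %s: %s", path,
                                            conditionMessage(e)),
                                    call. = FALSE))
  invisible(path)
}
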