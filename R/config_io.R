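# YAML (de)serialization of rule configurations. The file mirrors the
# rule_config structure with one top-level section per subtype, so one file
# can configure the whole pipeline:
#
# ABR:
#   extrema_window: 4
#   amplitude_override_ratio: 1.5
#   filter: {low_pass_hz: 1500, high_pass_hz: 150, fir_order: 100,
#            butter_order: 2, zero_phase: true}
#   intervals:
#     I: {polarity: peak, core: [1, 2], expanded: [0.5, 2.5]}
#     ...
#   gaps:
#     - {from: I, to: III, range: [1, 3]}

config_to_list <- function(cfg) {
  list(
    extrema_window = cfg$extrema_window,
    amplitude_override_ratio = cfg$amplitude_override_ratio,
    min_rel_amplitude = cfg$min_rel_amplitude,
    pam_window_ms = cfg$pam_window_ms,
    pam_ratio = cfg$pam_ratio,
    filter = unclass(cfg$filter),
    intervals = lapply(cfg$interval_rules, function(r) {
      out <- list(polarity = r$polarity, core = r$core_ms,
                  expanded = r$expanded_ms)
      if (!is.na(r$hard_cap_ms)) out$hard_cap <- r$hard_cap_ms
      out
    }),
    gaps = lapply(cfg$inter_wave_rules, function(r) {
      list(from = r$from_label, to = r$to_label, range = r$allowed_gap_ms)
    })
  )
}

list_to_config <- function(subtype, x) {
  rules <- lapply(names(x$intervals), function(lbl) {
    iv <- x$intervals[[lbl]]
    wave_interval_rule(lbl, iv$polarity, unlist(iv$core), unlist(iv$expanded),
                       if (is.null(iv$hard_cap)) NA_real_ else iv$hard_cap)
  })
  names(rules) <- names(x$intervals)
  gaps <- lapply(x$gaps, function(g) {
    inter_wave_rule(g$from, g$to, unlist(g$range))
  })
  f <- x$filter
  rule_config(
    subtype, rules, gaps,
    amplitude_override_ratio = x$amplitude_override_ratio,
    min_rel_amplitude = x$min_rel_amplitude,
    extrema_window = x$extrema_window,
    filter = display_filter_spec(f$low_pass_hz, f$high_pass_hz,
                                 f$fir_order, f$butter_order, f$zero_phase),
    pam_window_ms = unlist(x$pam_window_ms),
    pam_ratio = x$pam_ratio
  )
}

#' Write rule configurations to a YAML file
#'
#' @param configs Named list of [rule_config()] objects, names `"ABR"` /
#'   `"AMLR"`; defaults to both subtypes' shipped defaults.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_config_yaml <- function(configs = list(ABR = default_rule_config("ABR"),
                                                  AMLR = default_rule_config("AMLR")),
                                   path) {
  yaml::write_yaml(lapply(configs, config_to_list), path)
  invisible(path)
}

#' Read rule configurations from a YAML file
#'
#' Sections absent from the file fall back to [default_rule_config()], as do
#' omitted keys inside a section, so a file may override a single interval.
#'
#' @param path YAML file written by [write_rule_config_yaml()] (or edited by
#'   hand).
#' @return Named list with elements `ABR` and `AMLR`, each a [rule_config()].
#' @export
read_rule_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  for (subtype in SUBTYPES) {
    base <- config_to_list(default_rule_config(subtype))
    user <- raw[[subtype]]
    merged <- utils::modifyList(base, if (is.null(user)) list() else user)
    out[[subtype]] <- list_to_config(subtype, merged)
  }
  out
}
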