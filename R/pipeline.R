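## Pipeline orchestration: the decision tree from ingest to wide export,
## driven by a single (YAML-serialisable) config list.

default_config <- function() {
  list(
    input = list(
      dialect = "lacytools",
      data = NULL,
      layout = NULL,
      metadata = NULL,
      sample_type_rules = NULL,     # named list regex -> type
      sample_type_mapping = NULL,
      sample_regex = NULL,
      split_mode = "letter_digit",
      rename_isomers = TRUE         # skyline only
    ),
    quality = list(
      mass_error_window = NULL,     # per-dialect defaults when NULL
      pattern_threshold = NULL,
      signal_threshold = NULL
    ),
    spectra_curation = list(
      strategy = "negative_control",  # negative_control | percentile | skip
      percentile = 95,
      normal = FALSE,
      control_type = "negative_control",
      excluded_types = c("pool", "blank", "negative_control", "standard"),
      missing_policy = "exclude",
      rule = "strict"
    ),
    analyte_curation = list(
      mode = "consensus",           # consensus | per_sample
      grouping = "all",             # all | group
      group_col = NULL,
      min_freq = 0.5,
      logic = "OR",
      subset_samples = NULL,
      min_group_n = 10,
      overrides = NULL
    ),
    traits = list(
      formulas = NULL,
      missing_analytes = "drop"
    ),
    outdir = NULL
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), merges it over the defaults and
#' validates keys and enumerations. Unknown keys and invalid values are
#' errors naming the offending key.
#'
#' @param config Path to a YAML config file, or a (possibly partial) config
#'   list.
#' @return The completed config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort_glyco(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")),
                "glycocurate_config")
  }
  for (section in names(config)) {
    if (is.list(base[[section]]) && !is.null(config[[section]])) {
      bad <- setdiff(names(config[[section]]), names(base[[section]]))
      if (length(bad) > 0) {
        abort_glyco(
          sprintf("unknown config key(s) in '%s': %s", section,
                  paste(bad, collapse = ", ")),
          "glycocurate_config"
        )
      }
      base[[section]] <- utils::modifyList(base[[section]],
                                           config[[section]],
                                           keep.null = TRUE)
    } else {
      base[[section]] <- config[[section]]
    }
  }
  check_enum <- function(value, allowed, key) {
    if (!is.null(value) && !value %in% allowed) {
      abort_glyco(
        sprintf("config key '%s': invalid value '%s' (allowed: %s)", key,
                value, paste(allowed, collapse = ", ")),
        "glycocurate_config"
      )
    }
  }
  check_enum(base$input$dialect, c("lacytools", "skyline"), "input.dialect")
  check_enum(base$spectra_curation$strategy,
             c("negative_control", "percentile", "skip"),
             "spectra_curation.strategy")
  check_enum(base$spectra_curation$missing_policy, c("exclude", "zero"),
             "spectra_curation.missing_policy")
  check_enum(base$spectra_curation$rule, c("strict", "inclusive"),
             "spectra_curation.rule")
  check_enum(base$analyte_curation$mode, c("consensus", "per_sample"),
             "analyte_curation.mode")
  check_enum(base$analyte_curation$grouping, c("all", "group"),
             "analyte_curation.grouping")
  check_enum(base$analyte_curation$logic, c("OR", "AND"),
             "analyte_curation.logic")
  if (is.null(base$input$data)) {
    abort_glyco("config key 'input.data' is required", "glycocurate_config")
  }
  base
}

#' Run the full curation pipeline
#'
#' Executes ingest, annotation, quality evaluation, spectra curation,
#' analyte curation, total-area normalization and (optionally) trait
#' computation according to a config, returning every intermediate table.
#' When `config$outdir` is set, also writes the analyte-record export,
#' exclusion log, frequency table, wide export, run report JSON and — if
#' ggplot2 is available — the curation figures.
#'
#' @param config Config list or YAML path, see [load_config()].
#' @return A pipeline state list: `records`, `annotations`, `criteria`,
#'   `summaries`, `cutoffs`, `spectra_curated`, `frequencies`, `consensus`,
#'   `curated_records`, `rel_abund`, `formulas`, `traits`, `wide`,
#'   `settings` (the resolved config) and `outputs` (written paths).
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)

  ingest <- cli_ingest(cfg)
  records <- ingest$records
  annotations <- ingest$annotations

  spectra <- cli_curate_spectra(cfg, records)
  records <- evaluate_quality(records, spectra$criteria)
  analytes <- cli_curate_analytes(cfg, spectra$kept_records)

  criteria <- spectra$criteria
  summaries <- spectra$summaries
  cutoffs <- spectra$cutoffs
  spectra_curated <- spectra$spectra_curated
  frequencies <- analytes$frequencies
  consensus <- analytes$consensus
  curated_records <- analytes$curated_records

  rel_abund <- normalize_total_area(curated_records)

  formulas <- NULL
  traits <- NULL
  if (!is.null(cfg$traits$formulas)) {
    formulas <- parse_trait_formulas(cfg$traits$formulas)
    traits <- compute_traits(rel_abund, formulas,
                             missing_analytes = cfg$traits$missing_analytes)
  }
  wide <- export_wide(rel_abund, traits, annotations)

  state <- list(
    records = records, annotations = annotations, criteria = criteria,
    summaries = summaries, cutoffs = cutoffs,
    spectra_curated = spectra_curated, frequencies = frequencies,
    consensus = consensus, curated_records = curated_records,
    rel_abund = rel_abund, formulas = formulas, traits = traits,
    wide = wide, settings = cfg, outputs = NULL
  )
  if (!is.null(cfg$outdir)) {
    state$outputs <- write_pipeline_outputs(state, cfg$outdir)
  }
  state
}

write_pipeline_outputs <- function(state, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    records = file.path(outdir, "analyte_records.csv"),
    exclusion_log = file.path(outdir, "spectra_exclusion_log.csv"),
    frequencies = file.path(outdir, "analyte_frequencies.csv"),
    rel_abund = file.path(outdir, "relative_abundances.csv"),
    wide = file.path(outdir, "curated_wide.csv"),
    report = file.path(outdir, "report.json")
  )
  readr::write_csv(state$records, paths$records, na = "")
  log <- spectra_exclusion_log(state$spectra_curated)
  readr::write_csv(log, paths$exclusion_log, na = "")
  readr::write_csv(state$frequencies, paths$frequencies, na = "")
  readr::write_csv(state$rel_abund, paths$rel_abund, na = "")
  readr::write_csv(state$wide, paths$wide, na = "")
  write_report(state, paths$report)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    paths$spectra_plot <- file.path(outdir, "spectra_curation.png")
    p <- plot_spectra_curation(state$summaries, state$cutoffs)
    ggplot2::ggsave(paths$spectra_plot, p, width = 9, height = 4.5, dpi = 120)
    paths$frequency_plot <- file.path(outdir, "analyte_frequencies.png")
    p2 <- plot_analyte_frequencies(
      state$frequencies,
      min_freq = state$settings$analyte_curation$min_freq
    )
    ggplot2::ggsave(paths$frequency_plot, p2, width = 10, height = 5,
                    dpi = 120)
  }
  paths
}
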