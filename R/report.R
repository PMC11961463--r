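#' Export the curated dataset in wide format
#'
#' One row per sample; columns ordered metadata first, then glycosylation
#' traits, then per-analyte relative abundances (site-prefixed analyte
#' names). Samples excluded for a site at spectra curation appear with
#' missing values in that site's columns — rows are never dropped silently.
#' Analyte columns clashing with metadata column names are suffixed
#' `"_abundance"` with a warning.
#'
#' @param rel_abund Relative-abundance table from [normalize_total_area()].
#' @param traits Optional trait table from [compute_traits()].
#' @param annotations Sample annotation tibble (`sample_id` plus metadata
#'   columns); defines the exported rows.
#' @param path Optional CSV path.
#' @return The wide tibble, invisibly when `path` is given.
#' @export
export_wide <- function(rel_abund, traits = NULL, annotations = NULL,
                        path = NULL) {
  wide_ra <- tidyr::pivot_wider(
    dplyr::arrange(rel_abund, .data$site, .data$glycan),
    id_cols = "sample_id", names_from = "analyte",
    values_from = "relative_abundance"
  )
  if (is.null(annotations)) {
    annotations <- tibble::tibble(sample_id = unique(rel_abund$sample_id))
  }
  annotations <- dplyr::distinct(tibble::as_tibble(annotations))
  clash <- intersect(names(annotations), setdiff(names(wide_ra), "sample_id"))
  if (length(clash) > 0) {
    rlang::warn(
      sprintf("analyte column(s) clash with metadata, suffixed '_abundance': %s",
              paste(clash, collapse = ", ")),
      class = "glycocurate_column_clash"
    )
    names(wide_ra)[match(clash, names(wide_ra))] <-
      paste0(clash, "_abundance")
  }
  out <- annotations
  if (!is.null(traits)) {
    tclash <- intersect(names(annotations), setdiff(names(traits),
                                                    "sample_id"))
    if (length(tclash) > 0) {
      rlang::warn(
        sprintf("trait column(s) clash with metadata, suffixed '_trait': %s",
                paste(tclash, collapse = ", ")),
        class = "glycocurate_column_clash"
      )
      names(traits)[match(tclash, names(traits))] <- paste0(tclash, "_trait")
    }
    out <- dplyr::left_join(out, traits, by = "sample_id")
  }
  out <- dplyr::left_join(out, wide_ra, by = "sample_id")
  if (!is.null(path)) {
    readr::write_csv(out, path, na = "")
    return(invisible(out))
  }
  out
}

#' Write a machine-readable run report
#'
#' The JSON report captures everything needed to replicate the curation:
#' package version, input files with MD5 digests, every setting, the
#' per-site cutoffs with provenance, exclusion counts per sample type, the
#' consensus list with per-group frequencies and override flags, and the
#' trait formulas. Re-running [run_pipeline()] on the report's recorded
#' settings reproduces the kept sets and exports exactly; the timestamp is
#' the only field that differs between identical runs.
#'
#' @param state A pipeline state list from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(state, path) {
  settings <- drop_nulls(state$settings)
  input_files <- Filter(
    function(p) is.character(p) && length(p) == 1 && file.exists(p),
    settings$input[c("data", "layout", "metadata", "sample_type_mapping")]
  )
  digests <- lapply(input_files, function(p) unname(tools::md5sum(p)))
  excl <- spectra_exclusion_log(state$spectra_curated)
  report <- list(
    tool = "glycocurate",
    version = as.character(utils::packageVersion("glycocurate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(paths = input_files, md5 = digests),
    settings = settings,
    cutoffs = state$cutoffs,
    exclusions = list(
      n_excluded = sum(!state$spectra_curated$keep),
      by_sample_type = attr(excl, "by_sample_type")
    ),
    consensus = if (!is.null(state$consensus))
      tibble::as_tibble(state$consensus),
    trait_formulas = if (!is.null(state$formulas))
      lapply(state$formulas, format_trait_formula)
  )
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read back a run report
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The report as a list; `$settings` can be passed to
#'   [run_pipeline()] to replay the run.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
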