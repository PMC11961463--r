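#' Quality criteria for analyte curation
#'
#' Bundles the three per-analyte quality cutoffs. The defaults are the
#' empirically established values for each quantitation dialect:
#' LaCyTools — mass accuracy -20 to +20 ppm, isotopic pattern quality (IPQ)
#' at most 0.2 (0 is a perfect match), signal-to-noise at least 9;
#' Skyline — mass accuracy -2 to +2 ppm, isotope dot product at least 0.9
#' (1 is a perfect match), total MS1 area above 0.
#'
#' Score directionality differs between the dialects: the IPQ measures the
#' deviation from the theoretical isotopologue pattern (lower is better),
#' the isotope dot product its similarity (higher is better). Window and
#' thresholds are inclusive, except the Skyline area threshold which is
#' strict (`>`), so the default of 0 still rejects zero-area analytes.
#'
#' @param dialect `"lacytools"` or `"skyline"`.
#' @param mass_error_window Numeric length-2, ppm window `[low, high]`.
#' @param pattern_threshold IPQ maximum (lacytools) or isotope dot product
#'   minimum (skyline).
#' @param signal_threshold Signal-to-noise minimum (lacytools) or total-area
#'   lower bound, strict (skyline).
#' @return An object of class `quality_criteria`.
#' @export
quality_criteria <- function(dialect = c("lacytools", "skyline"),
                             mass_error_window = NULL,
                             pattern_threshold = NULL,
                             signal_threshold = NULL) {
  dialect <- match.arg(dialect)
  defaults <- switch(dialect,
    lacytools = list(mass_error_window = c(-20, 20),
                     pattern_threshold = 0.2, signal_threshold = 9),
    skyline = list(mass_error_window = c(-2, 2),
                   pattern_threshold = 0.9, signal_threshold = 0)
  )
  out <- list(
    dialect = dialect,
    mass_error_window = mass_error_window %||% defaults$mass_error_window,
    pattern_threshold = pattern_threshold %||% defaults$pattern_threshold,
    signal_threshold = signal_threshold %||% defaults$signal_threshold
  )
  if (length(out$mass_error_window) != 2 ||
      out$mass_error_window[1] >= out$mass_error_window[2]) {
    abort_glyco("mass_error_window must be c(low, high) with low < high",
                "glycocurate_criteria")
  }
  if (!all(is.finite(c(out$pattern_threshold, out$signal_threshold)))) {
    abort_glyco("quality thresholds must be finite", "glycocurate_criteria")
  }
  structure(out, class = "quality_criteria")
}

#' @export
print.quality_criteria <- function(x, ...) {
  cat(sprintf(
    "Quality criteria (%s): mass error [%g, %g] ppm; pattern %s %g; signal %s %g\n",
    x$dialect, x$mass_error_window[1], x$mass_error_window[2],
    if (x$dialect == "lacytools") "<=" else ">=", x$pattern_threshold,
    if (x$dialect == "lacytools") ">=" else ">", x$signal_threshold
  ))
  invisible(x)
}

#' Evaluate the three quality criteria per analyte record
#'
#' Adds the pass flags `pass_mass`, `pass_pattern`, `pass_signal` and their
#' conjunction `pass_overall` to the record table. A missing value in any
#' criterion — or a missing intensity — fails the overall check: a quantity
#' without its quality metrics is not trustworthy.
#'
#' @param records Analyte-record tibble.
#' @param criteria A [quality_criteria()] object matching the records'
#'   dialect.
#' @return The records with four logical pass-flag columns appended.
#' @export
evaluate_quality <- function(records, criteria) {
  stopifnot(inherits(criteria, "quality_criteria"))
  dialects <- unique(records$dialect)
  if (length(dialects) > 1 || !identical(dialects, criteria$dialect)) {
    abort_glyco(
      sprintf("records dialect (%s) does not match criteria dialect (%s)",
              paste(dialects, collapse = ","), criteria$dialect),
      "glycocurate_criteria"
    )
  }
  w <- criteria$mass_error_window
  records$pass_mass <- !is.na(records$mass_error_ppm) &
    records$mass_error_ppm >= w[1] & records$mass_error_ppm <= w[2]
  if (criteria$dialect == "lacytools") {
    records$pass_pattern <- !is.na(records$pattern_score) &
      records$pattern_score <= criteria$pattern_threshold
    records$pass_signal <- !is.na(records$signal_measure) &
      records$signal_measure >= criteria$signal_threshold
  } else {
    records$pass_pattern <- !is.na(records$pattern_score) &
      records$pattern_score >= criteria$pattern_threshold
    records$pass_signal <- !is.na(records$signal_measure) &
      records$signal_measure > criteria$signal_threshold
  }
  records$pass_overall <- records$pass_mass & records$pass_pattern &
    records$pass_signal & !is.na(records$intensity)
  records
}

#' Summarise each (sample, site) measurement for spectra curation
#'
#' Reduces the per-analyte pass flags of each spectrum — one (sample,
#' glycosylation site) measurement — to the two curation dimensions: the sum
#' intensity of all analytes passing the quality criteria, and the fraction
#' of the site's targeted analyte-charge combinations that pass. The
#' denominator is always the full targeted extraction list for the site,
#' regardless of how many analytes were detected in a given sample.
#'
#' @param records Analyte-record tibble; pass flags are computed on the fly
#'   when `criteria` is given, otherwise they must already be present.
#' @param criteria Optional [quality_criteria()].
#' @param targeted_list Optional tibble (`site`, `glycan`, `charge`)
#'   enumerating the targeted extraction list; defaults to all analyte-charge
#'   combinations present in `records`. Records outside the list are an
#'   error: the extraction list is authoritative.
#' @return Tibble with one row per (sample, site): `sum_intensity`,
#'   `passing_fraction`, `n_targeted`, `n_passing` and `has_values`
#'   (FALSE when the site yielded no values at all for the sample).
#'   `sample_type` and `plate` are carried along when present.
#' @export
summarize_spectra <- function(records, criteria = NULL, targeted_list = NULL) {
  if (!is.null(criteria)) {
    records <- evaluate_quality(records, criteria)
  }
  assert_columns(records, c("sample_id", "site", "glycan", "charge",
                            "intensity", "pass_overall"), "record table")
  if (is.null(targeted_list)) {
    targeted_list <- dplyr::distinct(records, .data$site, .data$glycan,
                                     .data$charge)
  } else {
    targeted_list <- dplyr::distinct(
      tibble::as_tibble(targeted_list), .data$site, .data$glycan, .data$charge
    )
    stray <- dplyr::anti_join(
      dplyr::distinct(records, .data$site, .data$glycan, .data$charge),
      targeted_list, by = c("site", "glycan", "charge")
    )
    if (nrow(stray) > 0) {
      abort_glyco(
        sprintf("record(s) outside the targeted extraction list: %s",
                paste(paste0(stray$site, stray$glycan, "_", stray$charge),
                      collapse = ", ")),
        "glycocurate_targeted_list"
      )
    }
  }
  n_targeted <- dplyr::count(targeted_list, .data$site, name = "n_targeted")

  per <- dplyr::group_by(records, .data$sample_id, .data$site)
  per <- dplyr::summarise(
    per,
    n_passing = sum(.data$pass_overall, na.rm = TRUE),
    sum_intensity = sum(.data$intensity[.data$pass_overall], na.rm = TRUE),
    has_values = any(!is.na(.data$intensity)),
    .groups = "drop"
  )
  # complete the sample x site grid: a sample with no rows at all for a site
  # still represents a (failed) measurement
  grid <- tidyr::expand_grid(
    sample_id = unique(records$sample_id),
    site = unique(n_targeted$site)
  )
  per <- dplyr::left_join(grid, per, by = c("sample_id", "site"))
  per$n_passing[is.na(per$n_passing)] <- 0L
  per$sum_intensity[is.na(per$sum_intensity)] <- 0
  per$has_values[is.na(per$has_values)] <- FALSE
  per <- dplyr::left_join(per, n_targeted, by = "site")
  per$passing_fraction <- ifelse(per$n_targeted > 0,
                                 per$n_passing / per$n_targeted, 0)
  ann_cols <- intersect(c("sample_type", "plate", "well"), names(records))
  if (length(ann_cols) > 0) {
    ann <- dplyr::distinct(records, .data$sample_id,
                           dplyr::across(dplyr::all_of(ann_cols)))
    per <- dplyr::left_join(per, ann, by = "sample_id")
  }
  dplyr::select(per, "sample_id", "site", "sum_intensity", "passing_fraction",
                "n_targeted", "n_passing", "has_values",
                dplyr::all_of(ann_cols))
}
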