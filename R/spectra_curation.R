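## Spectra curation: per-site 2-D cutoffs on (sum intensity, passing
## fraction) and exclusion of whole (sample, site) measurements.

new_cutoffs <- function(site, intensity_cutoff, fraction_cutoff, strategy,
                        percentile = NA_real_, normal_assumption = FALSE,
                        control_type = NA_character_, n_used = NA_integer_) {
  tibble::tibble(
    site = site,
    intensity_cutoff = intensity_cutoff,
    fraction_cutoff = fraction_cutoff,
    strategy = strategy,
    percentile = percentile,
    normal_assumption = normal_assumption,
    control_type = control_type,
    n_used = n_used
  )
}

#' Spectra-curation cutoffs from negative controls
#'
#' The recommended strategy: per glycosylation site, the cutoff in each
#' dimension (sum intensity, passing fraction) is a percentile of the values
#' observed in the negative-control measurements. Percentile 100 takes the
#' controls' maximum; the default of 95 trims potential outliers.
#' Percentiles use the linear-interpolation definition
#' (`stats::quantile(type = 7)`). With `normal = TRUE` a normal distribution
#' is assumed instead and the cutoff is `mean + z(percentile) * sd` of the
#' control values.
#'
#' Sites without any negative-control values get `-Inf` cutoffs — the
#' curation for such a site is identical to not applying curation — and a
#' warning.
#'
#' @param summaries Spectrum summaries from [summarize_spectra()] (must
#'   carry `sample_type`).
#' @param control_type Sample type of the negative controls.
#' @param percentile Percentile of included controls, in (0, 100].
#' @param normal Assume normality and use mean/sd instead of the empirical
#'   percentile.
#' @return A cutoff tibble, one row per site.
#' @export
cutoffs_from_negative_controls <- function(summaries,
                                           control_type = "negative_control",
                                           percentile = 95, normal = FALSE) {
  assert_columns(summaries, c("site", "sample_type", "sum_intensity",
                              "passing_fraction", "has_values"),
                 "spectrum summaries")
  stopifnot(percentile > 0, percentile <= 100)
  sites <- unique(summaries$site)
  rows <- lapply(sites, function(s) {
    ctl <- summaries[summaries$site == s &
                       summaries$sample_type == control_type &
                       summaries$has_values, ]
    if (nrow(ctl) == 0) {
      rlang::warn(
        sprintf(paste0("site '%s': no negative-control values; curation for ",
                       "this site is identical to not applying curation"), s),
        class = "glycocurate_no_controls"
      )
      return(new_cutoffs(s, -Inf, -Inf, "negative_control", percentile,
                         normal, control_type, 0L))
    }
    cut1d <- function(x) {
      if (normal) {
        sdx <- stats::sd(x)
        if (is.na(sdx)) sdx <- 0
        mean(x) + stats::qnorm(percentile / 100) * sdx
      } else {
        unname(stats::quantile(x, percentile / 100, type = 7))
      }
    }
    new_cutoffs(s, cut1d(ctl$sum_intensity), cut1d(ctl$passing_fraction),
                "negative_control", percentile, normal, control_type,
                nrow(ctl))
  })
  dplyr::bind_rows(rows)
}

#' Spectra-curation cutoffs from a fixed lowest percentile
#'
#' In the absence of adequate negative controls, a fixed portion of the
#' lowest-quality measurements is excluded: per site and per dimension, the
#' cutoff is the given percentile of the study samples' values. All control
#' and blank sample types must be excluded from the computation. Because the
#' percentile applies to each dimension separately, the overall fraction of
#' excluded spectra is slightly higher than the percentile. Percentile 0
#' disables exclusion (`-Inf` cutoffs).
#'
#' @param summaries Spectrum summaries (with `sample_type`).
#' @param percentile Percentile in [0, 100).
#' @param excluded_types Sample types excluded from the computation
#'   (controls, blanks, pools).
#' @return A cutoff tibble, one row per site.
#' @export
cutoffs_from_percentile <- function(summaries, percentile = 2,
                                    excluded_types = c("pool", "blank",
                                                       "negative_control",
                                                       "standard")) {
  assert_columns(summaries, c("site", "sample_type", "sum_intensity",
                              "passing_fraction", "has_values"),
                 "spectrum summaries")
  stopifnot(percentile >= 0, percentile < 100)
  keep <- !(summaries$sample_type %in% excluded_types) & summaries$has_values
  if (!any(keep)) {
    abort_glyco("all samples excluded by type; cannot compute percentile cutoffs",
                "glycocurate_cutoffs")
  }
  sites <- unique(summaries$site)
  rows <- lapply(sites, function(s) {
    x <- summaries[keep & summaries$site == s, ]
    if (nrow(x) == 0 || percentile == 0) {
      return(new_cutoffs(s, -Inf, -Inf, "percentile", percentile))
    }
    new_cutoffs(
      s,
      unname(stats::quantile(x$sum_intensity, percentile / 100, type = 7)),
      unname(stats::quantile(x$passing_fraction, percentile / 100, type = 7)),
      "percentile", percentile,
      n_used = nrow(x)
    )
  })
  dplyr::bind_rows(rows)
}

#' No-op cutoffs for skipping spectra curation
#'
#' @param sites Character vector of glycosylation sites.
#' @return A cutoff tibble with strategy `"skip"`; every measurement passes.
#' @export
cutoffs_skip <- function(sites) {
  new_cutoffs(unique(sites), -Inf, -Inf, "skip")
}

#' Apply spectra curation
#'
#' A measurement is kept iff its sum intensity and passing fraction both lie
#' strictly above the site's cutoffs (`rule = "strict"`, the default — so
#' the very controls defining a maximum-based cutoff are themselves
#' excluded); `rule = "inclusive"` keeps measurements at the cutoff.
#' Measurements without values are excluded under the default
#' `missing_policy = "exclude"`, or treated as zeros under `"zero"` (and
#' then excluded whenever the cutoffs are non-negative, given the strict
#' rule). The strategy `"skip"` keeps everything.
#'
#' @param summaries Spectrum summaries.
#' @param cutoffs Cutoff tibble (one row per curated site).
#' @param missing_policy `"exclude"` or `"zero"`.
#' @param rule `"strict"` (`>`) or `"inclusive"` (`>=`).
#' @return The summaries with logical `keep` and character `reason` columns
#'   (`reason` is `NA` for kept measurements; otherwise one of
#'   `"no_values"`, `"low_intensity"`, `"low_fraction"`,
#'   `"low_intensity_and_fraction"`).
#' @export
apply_spectra_curation <- function(summaries, cutoffs,
                                   missing_policy = c("exclude", "zero"),
                                   rule = c("strict", "inclusive")) {
  missing_policy <- match.arg(missing_policy)
  rule <- match.arg(rule)
  assert_columns(cutoffs, c("site", "intensity_cutoff", "fraction_cutoff",
                            "strategy"), "cutoffs")
  out <- dplyr::left_join(
    summaries,
    cutoffs[c("site", "intensity_cutoff", "fraction_cutoff", "strategy")],
    by = "site"
  )
  # uncurated sites behave like strategy "skip"
  out$strategy[is.na(out$strategy)] <- "skip"
  out$intensity_cutoff[is.na(out$intensity_cutoff)] <- -Inf
  out$fraction_cutoff[is.na(out$fraction_cutoff)] <- -Inf

  si <- out$sum_intensity
  pf <- out$passing_fraction
  if (missing_policy == "zero") {
    si[!out$has_values] <- 0
    pf[!out$has_values] <- 0
  }
  gt <- if (rule == "strict") `>` else `>=`
  ok_int <- gt(si, out$intensity_cutoff)
  ok_frac <- gt(pf, out$fraction_cutoff)
  keep <- ok_int & ok_frac
  reason <- dplyr::case_when(
    !keep & !ok_int & !ok_frac ~ "low_intensity_and_fraction",
    !keep & !ok_int ~ "low_intensity",
    !keep ~ "low_fraction"
  )
  if (missing_policy == "exclude") {
    keep[!out$has_values] <- FALSE
    reason[!out$has_values] <- "no_values"
  }
  skip <- out$strategy == "skip"
  keep[skip] <- TRUE
  reason[skip] <- NA_character_
  out$keep <- keep
  out$reason <- reason
  out$intensity_cutoff <- NULL
  out$fraction_cutoff <- NULL
  out$strategy <- NULL
  out
}

#' Exclusion log of a spectra-curation result
#'
#' @param curated Output of [apply_spectra_curation()].
#' @return Tibble of excluded measurements (`sample_id`, `site`,
#'   `sample_type` when present, `reason`), plus a per-sample-type summary
#'   in attribute `"by_sample_type"`.
#' @export
spectra_exclusion_log <- function(curated) {
  cols <- intersect(c("sample_id", "site", "sample_type", "reason"),
                    names(curated))
  log <- dplyr::select(curated[!curated$keep, ], dplyr::all_of(cols))
  if ("sample_type" %in% cols) {
    by_type <- dplyr::count(log, .data$sample_type, .data$site, .data$reason,
                            name = "n_excluded")
  } else {
    by_type <- dplyr::count(log, .data$site, .data$reason, name = "n_excluded")
  }
  attr(log, "by_sample_type") <- by_type
  log
}

#' Restrict records to measurements kept by spectra curation
#'
#' @param records Analyte-record tibble.
#' @param curated Output of [apply_spectra_curation()].
#' @return Records of kept (sample, site) measurements only.
#' @export
filter_kept_records <- function(records, curated) {
  kept <- curated[curated$keep, c("sample_id", "site")]
  dplyr::semi_join(records, kept, by = c("sample_id", "site"))
}
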