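## Analyte curation: per-analyte-and-charge passing frequencies across the
## spectra-curation-surviving measurements, consensus-list construction with
## AND/OR merging, manual overrides, and removal of failing analytes.

#' Passing frequency of each analyte-charge combination
#'
#' For every (site, composition, charge) entry, computes the relative
#' frequency of measurements in which it passes all three quality criteria.
#' Frequencies are computed per charge state individually, since charge
#' states of one glycopeptide can differ markedly in quality. The
#' denominator for a site counts only measurements that survived spectra
#' curation and have values for that site.
#'
#' @param records Records of kept measurements (see [filter_kept_records()])
#'   with pass flags from [evaluate_quality()].
#' @param grouping `"all"` (one scope covering every measurement),
#'   `"per_sample"` (one scope per sample; frequencies are 0 or 1), or
#'   `"group"` (one scope per level of `group_col`).
#' @param group_col Column of `records` holding the biological group, for
#'   `grouping = "group"`.
#' @param subset_samples Optional character vector of sample IDs; only these
#'   measurements inform the frequencies (e.g. curate on antigen-specific
#'   measurements only, then apply the list to all).
#' @param min_group_n Minimum recommended group size (default 10); smaller
#'   groups trigger a warning.
#' @return Tibble (`scope`, `site`, `glycan`, `charge`, `n_pass`,
#'   `n_eligible`, `frequency`).
#' @export
passing_frequency <- function(records,
                              grouping = c("all", "per_sample", "group"),
                              group_col = NULL, subset_samples = NULL,
                              min_group_n = 10) {
  grouping <- match.arg(grouping)
  assert_columns(records, c("sample_id", "site", "glycan", "charge",
                            "pass_overall", "intensity"), "record table")
  if (!is.null(subset_samples)) {
    records <- records[records$sample_id %in% subset_samples, ]
    if (nrow(records) == 0) {
      abort_glyco("subset_samples matches no measurements",
                  "glycocurate_frequency")
    }
  }
  records$scope <- switch(grouping,
    all = "all",
    per_sample = records$sample_id,
    group = {
      if (is.null(group_col) || !group_col %in% names(records)) {
        abort_glyco("grouping = 'group' requires an existing group_col",
                    "glycocurate_frequency")
      }
      as.character(records[[group_col]])
    }
  )
  records <- records[!is.na(records$scope), ]

  # eligibility: per (scope, site), the measurements with values
  eligible <- dplyr::distinct(
    records[!is.na(records$intensity), ],
    .data$scope, .data$site, .data$sample_id
  )
  eligible <- dplyr::count(eligible, .data$scope, .data$site,
                           name = "n_eligible")
  if (grouping == "group") {
    sizes <- dplyr::count(dplyr::distinct(records, .data$scope,
                                          .data$sample_id),
                          .data$scope, name = "n_samples")
    small <- sizes[sizes$n_samples < min_group_n, ]
    if (nrow(small) > 0) {
      rlang::warn(
        sprintf("biological group(s) below the recommended minimum of %d samples: %s",
                min_group_n,
                paste(sprintf("%s (n=%d)", small$scope, small$n_samples),
                      collapse = ", ")),
        class = "glycocurate_small_group"
      )
    }
  }
  passes <- dplyr::group_by(records, .data$scope, .data$site, .data$glycan,
                            .data$charge)
  passes <- dplyr::summarise(passes,
                             n_pass = sum(.data$pass_overall, na.rm = TRUE),
                             .groups = "drop")
  out <- dplyr::left_join(passes, eligible, by = c("scope", "site"))
  out$n_eligible[is.na(out$n_eligible)] <- 0L
  out$frequency <- ifelse(out$n_eligible > 0, out$n_pass / out$n_eligible,
                          NA_real_)
  out
}

#' Build a consensus analyte list from passing frequencies
#'
#' Each scope (biological group, or `"all"`) retains the entries whose
#' passing frequency reaches `min_freq` (inclusive, so a 50% cutoff keeps an
#' analyte passing in exactly half the eligible measurements). Multiple
#' scopes are merged with OR logic (union — preserves group-specific
#' analytes) or AND logic (intersection). Typical `min_freq` values are 0.8
#' for high-quality and 0.5 for medium- to low-quality datasets.
#'
#' @param freq Frequency table from [passing_frequency()].
#' @param min_freq Minimum passing frequency in [0, 1].
#' @param logic `"OR"` or `"AND"`.
#' @return A `consensus_list`: tibble (`site`, `glycan`, `charge`,
#'   `override`) of retained entries, with per-scope frequencies in wide
#'   columns `freq_<scope>`; the full candidate table is kept in attribute
#'   `"candidates"`, and `min_freq`/`logic` as attributes.
#' @export
build_consensus <- function(freq, min_freq, logic = c("OR", "AND")) {
  logic <- match.arg(logic)
  stopifnot(min_freq >= 0, min_freq <= 1)
  freq$in_list <- !is.na(freq$frequency) & freq$frequency >= min_freq
  wide <- tidyr::pivot_wider(
    freq, id_cols = c("site", "glycan", "charge"),
    names_from = "scope", values_from = "frequency", names_prefix = "freq_"
  )
  membership <- dplyr::group_by(freq, .data$site, .data$glycan, .data$charge)
  membership <- dplyr::summarise(
    membership,
    n_scopes_in = sum(.data$in_list),
    n_scopes = dplyr::n(),
    .groups = "drop"
  )
  retained <- switch(logic,
    OR = membership$n_scopes_in > 0,
    AND = membership$n_scopes_in == membership$n_scopes
  )
  candidates <- dplyr::left_join(membership, wide,
                                 by = c("site", "glycan", "charge"))
  candidates$retained_auto <- retained
  out <- candidates[retained, ]
  out$override <- FALSE
  if (nrow(out) == 0) {
    abort_glyco("consensus list is empty; downstream normalization is undefined",
                "glycocurate_consensus")
  }
  structure(
    dplyr::select(out, -"n_scopes_in", -"n_scopes", -"retained_auto"),
    candidates = candidates, min_freq = min_freq, logic = logic,
    class = c("consensus_list", class(out))
  )
}

#' Apply manual overrides to a consensus list
#'
#' Manual checks (e.g. identified false positives, or border cases worth
#' keeping) are expressed as a table of entries with a logical `keep`
#' column; the override wins over the automated result and is flagged in
#' the `override` column. The operation is idempotent.
#'
#' @param consensus A `consensus_list` from [build_consensus()].
#' @param overrides Data frame / CSV / XLSX with columns `site`, `glycan`,
#'   `charge`, `keep`. Entries must exist among the curation candidates.
#' @return The modified `consensus_list`.
#' @export
apply_overrides <- function(consensus, overrides) {
  overrides <- read_table_any(overrides, "override table")
  if (nrow(overrides) == 0) {
    return(consensus)
  }
  assert_columns(overrides, c("site", "glycan", "charge", "keep"),
                 "override table")
  overrides$keep <- as.logical(overrides$keep)
  candidates <- attr(consensus, "candidates")
  known <- dplyr::semi_join(overrides, candidates,
                            by = c("site", "glycan", "charge"))
  if (nrow(known) < nrow(overrides)) {
    unknown <- dplyr::anti_join(overrides, candidates,
                                by = c("site", "glycan", "charge"))
    abort_glyco(
      sprintf("override(s) reference unknown analyte entries: %s",
              paste(paste0(unknown$site, unknown$glycan, "_", unknown$charge),
                    collapse = ", ")),
      "glycocurate_override"
    )
  }
  atts <- attributes(consensus)
  out <- tibble::as_tibble(consensus)
  # drop entries overridden to keep = FALSE
  drop <- overrides[!overrides$keep, c("site", "glycan", "charge")]
  out <- dplyr::anti_join(out, drop, by = c("site", "glycan", "charge"))
  # add entries overridden to keep = TRUE that are not yet retained
  add <- overrides[overrides$keep, c("site", "glycan", "charge")]
  add <- dplyr::anti_join(add, out, by = c("site", "glycan", "charge"))
  if (nrow(add) > 0) {
    add <- dplyr::left_join(
      add,
      dplyr::select(candidates, -"n_scopes_in", -"n_scopes",
                    -"retained_auto"),
      by = c("site", "glycan", "charge")
    )
    add$override <- TRUE
    out <- dplyr::bind_rows(out, add)
  }
  # flag entries whose retention goes against the automated result
  auto <- candidates[candidates$retained_auto,
                     c("site", "glycan", "charge")]
  out$override <- interaction(out$site, out$glycan, out$charge) %in%
    interaction(overrides$site, overrides$glycan, overrides$charge) &
    !(interaction(out$site, out$glycan, out$charge) %in%
        interaction(auto$site, auto$glycan, auto$charge))
  if (nrow(out) == 0) {
    abort_glyco("overrides emptied the consensus list", "glycocurate_consensus")
  }
  attributes(out) <- utils::modifyList(
    atts, list(row.names = attr(out, "row.names"), names = names(out))
  )
  out
}

#' Remove analytes failing curation from the record table
#'
#' In consensus mode, every record whose (site, composition, charge) entry
#' is not on the consensus list is removed from all samples. In per-sample
#' mode, each sample keeps exactly the entries that pass the quality
#' criteria in that sample.
#'
#' @param records Records of kept measurements, with pass flags.
#' @param consensus A `consensus_list`, or `NULL` for per-sample mode.
#' @param per_sample Logical; curate each sample by its own quality check.
#' @return The curated record table.
#' @export
apply_analyte_curation <- function(records, consensus = NULL,
                                   per_sample = FALSE) {
  if (per_sample) {
    return(records[records$pass_overall, ])
  }
  stopifnot(!is.null(consensus))
  dplyr::semi_join(records, consensus, by = c("site", "glycan", "charge"))
}
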