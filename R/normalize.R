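#' Total-area normalization per glycosylation site
#'
#' Expresses each curated analyte as a percentage of the summed signal of
#' all retained analytes of its glycosylation site, per sample. Retained
#' charge states of one analyte are summed before normalization; sites are
#' normalized independently. A (sample, site) pair whose retained analytes
#' sum to zero yields missing values, never a division by zero.
#'
#' @param curated_records Record table after analyte curation.
#' @return Tibble (`sample_id`, `site`, `glycan`, `analyte`,
#'   `relative_abundance`) with abundances in percent; per (sample, site)
#'   they sum to 100 (within numerical precision) whenever any signal was
#'   retained.
#' @export
normalize_total_area <- function(curated_records) {
  assert_columns(curated_records, c("sample_id", "site", "glycan",
                                    "intensity"), "curated records")
  if (any(curated_records$intensity < 0, na.rm = TRUE)) {
    abort_glyco("negative intensities cannot be normalized",
                "glycocurate_normalize")
  }
  # sum retained charge states of each analyte
  per_analyte <- dplyr::group_by(curated_records, .data$sample_id, .data$site,
                                 .data$glycan)
  per_analyte <- dplyr::summarise(
    per_analyte,
    intensity = if (all(is.na(.data$intensity))) NA_real_ else
      sum(.data$intensity, na.rm = TRUE),
    .groups = "drop"
  )
  per_site <- dplyr::group_by(per_analyte, .data$sample_id, .data$site)
  per_site <- dplyr::mutate(
    per_site,
    .total = sum(.data$intensity, na.rm = TRUE),
    relative_abundance = dplyr::if_else(
      .data$.total > 0, 100 * .data$intensity / .data$.total, NA_real_
    )
  )
  out <- dplyr::ungroup(per_site)
  out$analyte <- paste0(out$site, out$glycan)
  dplyr::select(out, "sample_id", "site", "glycan", "analyte",
                "relative_abundance")
}
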