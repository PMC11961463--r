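## Optional features: SIL-based absolute quantitation and plate-level
## repeatability (CV) metrics.

#' Absolute protein quantitation from stable-isotope-labeled spikes
#'
#' For each quantifying peptide, the light/heavy intensity ratio times the
#' spiked amount gives a per-peptide protein quantity; the protein quantity
#' per sample is the median over peptides. Pairwise Pearson correlations of
#' the per-peptide quantities across samples serve as a quality check.
#'
#' @param records Curated record table; light and heavy signals are summed
#'   per (sample, site).
#' @param sil_map Data frame / CSV with columns `peptide` (light site name),
#'   `heavy_site` (the SIL analyte's site name) and `spike_amount` (amount
#'   spiked, in the user's units).
#' @return A list with `quantities` (tibble `sample_id`, `peptide`,
#'   `quantity`), `summary` (tibble `sample_id`, `median_quantity`,
#'   `n_peptides`) and `correlations` (peptide-by-peptide Pearson matrix;
#'   empty for a single peptide).
#' @export
sil_quantify <- function(records, sil_map) {
  sil_map <- read_table_any(sil_map, "SIL map")
  assert_columns(sil_map, c("peptide", "heavy_site", "spike_amount"),
                 "SIL map")
  sums <- dplyr::group_by(records, .data$sample_id, .data$site)
  sums <- dplyr::summarise(
    sums, intensity = sum(.data$intensity, na.rm = TRUE), .groups = "drop"
  )
  rows <- list()
  for (i in seq_len(nrow(sil_map))) {
    pep <- sil_map$peptide[[i]]
    light <- sums[sums$site == pep, c("sample_id", "intensity")]
    heavy <- sums[sums$site == sil_map$heavy_site[[i]],
                  c("sample_id", "intensity")]
    joined <- dplyr::inner_join(light, heavy, by = "sample_id",
                                suffix = c("_light", "_heavy"))
    bad <- is.na(joined$intensity_heavy) | joined$intensity_heavy <= 0
    if (any(bad)) {
      rlang::warn(
        sprintf("peptide '%s': heavy signal missing or zero in %d sample(s); skipped there",
                pep, sum(bad)),
        class = "glycocurate_sil_heavy"
      )
    }
    joined <- joined[!bad, ]
    rows[[i]] <- tibble::tibble(
      sample_id = joined$sample_id,
      peptide = pep,
      quantity = joined$intensity_light / joined$intensity_heavy *
        sil_map$spike_amount[[i]]
    )
  }
  quantities <- dplyr::bind_rows(rows)
  summary <- dplyr::group_by(quantities, .data$sample_id)
  summary <- dplyr::summarise(
    summary,
    median_quantity = stats::median(.data$quantity),
    n_peptides = dplyr::n(),
    .groups = "drop"
  )
  peptides <- unique(quantities$peptide)
  if (length(peptides) >= 2) {
    wide <- tidyr::pivot_wider(quantities, id_cols = "sample_id",
                               names_from = "peptide",
                               values_from = "quantity")
    correlations <- stats::cor(as.matrix(wide[peptides]),
                               use = "pairwise.complete.obs",
                               method = "pearson")
  } else {
    correlations <- matrix(numeric(0), 0, 0)
  }
  list(quantities = quantities, summary = summary,
       correlations = correlations)
}

cv_percent <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  if (length(x) < 2 || m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Plate-level repeatability of technical replicates
#'
#' Derives technical variability from repeated measurements of a control
#' pool: per (plate, analyte), the mean relative abundance and CV
#' (100 * sd / mean, sample sd) over that plate's replicates. The median
#' intra-plate CV is taken over all (plate, analyte) cells with at least two
#' replicates; the median inter-plate CV is, per analyte, the CV of the
#' plate means, median over analytes (requires at least two plates).
#'
#' @param rel_abund Relative-abundance table from [normalize_total_area()].
#' @param annotations Tibble mapping `sample_id` to `sample_type` and
#'   `plate`.
#' @param control_type Sample type of the technical replicates (default
#'   `"pool"`).
#' @return A list with `per_plate` (tibble `plate`, `site`, `analyte`, `n`,
#'   `mean`, `cv`), `plate_means` (per analyte per plate),
#'   `median_intra_plate_cv` and `median_inter_plate_cv` (both percent).
#' @export
repeatability <- function(rel_abund, annotations, control_type = "pool") {
  assert_columns(annotations, c("sample_id", "sample_type", "plate"),
                 "annotations")
  ctl <- annotations[annotations$sample_type == control_type,
                     c("sample_id", "plate")]
  if (nrow(ctl) < 2) {
    abort_glyco(
      sprintf("need at least two '%s' replicate measurements", control_type),
      "glycocurate_repeatability"
    )
  }
  x <- dplyr::inner_join(rel_abund, ctl, by = "sample_id")
  per_plate <- dplyr::group_by(x, .data$plate, .data$site, .data$analyte)
  per_plate <- dplyr::summarise(
    per_plate,
    n = sum(!is.na(.data$relative_abundance)),
    mean = mean(.data$relative_abundance, na.rm = TRUE),
    cv = cv_percent(.data$relative_abundance),
    .groups = "drop"
  )
  plate_means <- per_plate[c("plate", "site", "analyte", "mean")]
  inter <- dplyr::group_by(plate_means, .data$site, .data$analyte)
  inter <- dplyr::summarise(inter, cv = cv_percent(.data$mean),
                            .groups = "drop")
  list(
    per_plate = per_plate,
    plate_means = plate_means,
    median_intra_plate_cv = stats::median(per_plate$cv, na.rm = TRUE),
    median_inter_plate_cv = stats::median(inter$cv, na.rm = TRUE)
  )
}
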