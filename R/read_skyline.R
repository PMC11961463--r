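## Skyline report dialect: one CSV row per precursor (protein, peptide,
## charge); samples column-wise as per-sample triplets
## "<sample> Isotope Dot Product", "<sample> Average mass error PPM",
## "<sample> Total area MS1".

SKYLINE_KEY_COLUMNS <- c("Protein name", "Peptide", "Precursor Charge")
SKYLINE_SUFFIXES <- c(
  pattern_score = "Isotope Dot Product",
  mass_error_ppm = "Average mass error PPM",
  intensity = "Total area MS1"
)

#' Read a Skyline-style report CSV
#'
#' Parses a Skyline report with the three key columns `"Protein name"`
#' (glycosylation site; by convention `"AB"` for released-glycan data),
#' `"Peptide"` (glycan composition label) and `"Precursor Charge"`, plus
#' per-sample column triplets holding the isotope dot product, average mass
#' error (ppm) and total MS1 area. The MS1 area serves as both the quantity
#' and the signal measure of each record.
#'
#' @param path Path to the report CSV.
#' @param sample_regex Optional regex; when given, sample names extracted
#'   from the triplet columns must match it (escape hatch for reports whose
#'   column prefixes carry extra annotation).
#' @param alphabet,mode Composition parsing options, see
#'   [split_analyte_name()]. The `"Peptide"` column is parsed as a bare
#'   composition label (no site prefix).
#' @return A tibble of analyte records (`dialect = "skyline"`); `pattern_score`
#'   is the isotope dot product (1 = perfect) and `signal_measure` the total
#'   MS1 area. `source_row` preserves the report row order used for isomer
#'   renaming, see [rename_isomers()].
#' @export
read_skyline <- function(path, sample_regex = NULL,
                         alphabet = glycan_alphabet, mode = "letter_digit") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  missing_keys <- setdiff(SKYLINE_KEY_COLUMNS, names(df))
  if (length(missing_keys) > 0) {
    abort_glyco(
      sprintf("Skyline report is missing required column(s): %s",
              paste(missing_keys, collapse = ", ")),
      "glycocurate_missing_column"
    )
  }
  triplets <- find_sample_triplets(names(df), sample_regex)
  if (nrow(triplets$samples) == 0) {
    abort_glyco(
      sprintf("Skyline report has no per-sample column triplet (need '%s')",
              paste(SKYLINE_SUFFIXES, collapse = "', '")),
      "glycocurate_missing_column"
    )
  }

  base <- tibble::tibble(
    site = as.character(df[["Protein name"]]),
    glycan_raw = as.character(df[["Peptide"]]),
    charge = as.integer(df[["Precursor Charge"]]),
    source_row = seq_len(nrow(df))
  )

  recs <- lapply(seq_len(nrow(triplets$samples)), function(i) {
    s <- triplets$samples$sample[[i]]
    out <- base
    out$measurement_file <- s
    out$pattern_score <- as.numeric(df[[triplets$samples$pattern_score[[i]]]])
    out$mass_error_ppm <- as.numeric(df[[triplets$samples$mass_error_ppm[[i]]]])
    out$intensity <- as.numeric(df[[triplets$samples$intensity[[i]]]])
    out
  })
  out <- dplyr::bind_rows(recs)
  parsed <- lapply(out$glycan_raw, parse_composition, alphabet = alphabet)
  out$glycan <- out$glycan_raw
  out$isomer_suffix <- vapply(parsed, `[[`, "", "isomer_suffix")
  out$analyte <- paste0(out$site, out$glycan)
  out$signal_measure <- out$intensity
  out$dialect <- "skyline"
  out$missing <- is.na(out$intensity)
  dplyr::select(
    out, "measurement_file", "analyte", "site", "glycan", "isomer_suffix",
    "charge", "intensity", "mass_error_ppm", "pattern_score",
    "signal_measure", "dialect", "missing", "source_row"
  )
}

find_sample_triplets <- function(cols, sample_regex = NULL) {
  out <- list()
  for (field in names(SKYLINE_SUFFIXES)) {
    suffix <- SKYLINE_SUFFIXES[[field]]
    hits <- grep(paste0(" ", suffix, "$"), cols, value = TRUE, fixed = FALSE)
    out[[field]] <- tibble::tibble(
      sample = sub(paste0(" ", suffix, "$"), "", hits),
      column = hits
    )
  }
  samples <- Reduce(intersect, lapply(out, function(x) x$sample))
  if (!is.null(sample_regex)) {
    samples <- samples[grepl(sample_regex, samples)]
  }
  all_seen <- unique(unlist(lapply(out, function(x) x$sample)))
  incomplete <- setdiff(if (is.null(sample_regex)) all_seen else
    all_seen[grepl(sample_regex, all_seen)], samples)
  if (length(incomplete) > 0) {
    abort_glyco(
      sprintf("sample(s) with incomplete column triplet: %s",
              paste(incomplete, collapse = ", ")),
      "glycocurate_missing_column"
    )
  }
  tbl <- tibble::tibble(sample = samples)
  for (field in names(SKYLINE_SUFFIXES)) {
    m <- match(samples, out[[field]]$sample)
    tbl[[field]] <- out[[field]]$column[m]
  }
  list(samples = tbl)
}
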