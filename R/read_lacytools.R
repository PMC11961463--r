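## LaCyTools summary dialect
##
## A summary file is a tab-separated text file organised in blocks, one block
## per (output type, charge state). Supported output types:
##
##   Analyte Intensity (Background Subtracted)
##   Mass Accuracy [ppm]
##   Isotopic Pattern Quality
##   S/N
##
## Block layout:
##   line 1: "<output type>\tcharge <k>+"
##   line 2: "\t<analyte 1>\t<analyte 2>..."            (header row)
##   lines : "<measurement file>\t<value>\t<value>..."  (one row per sample)
## Blocks are separated by one or more blank lines; leading/trailing blank
## lines are tolerated. All four blocks of a charge state must list identical
## samples and analytes. Blank cells denote missing values.

LACYTOOLS_MEASURES <- c(
  intensity = "Analyte Intensity (Background Subtracted)",
  mass_error_ppm = "Mass Accuracy [ppm]",
  pattern_score = "Isotopic Pattern Quality",
  signal_measure = "S/N"
)

#' Read a LaCyTools-style summary file
#'
#' Parses the block-structured summary text written by LaCyTools-style
#' quantitation (background-subtracted analyte intensity, mass accuracy in
#' ppm, isotopic pattern quality and signal-to-noise, per charge state) into
#' one long analyte-record table. Every (sample, analyte, charge) cell of the
#' targeted extraction grid yields one record; blank cells yield records with
#' missing values, never zeros.
#'
#' @param path Path to the summary text file.
#' @param alphabet Monosaccharide alphabet for composition parsing.
#' @param mode Analyte-name split rule, see [split_analyte_name()].
#' @return A tibble of analyte records with columns `measurement_file`,
#'   `analyte`, `site`, `glycan`, `isomer_suffix`, `charge`, `intensity`,
#'   `mass_error_ppm`, `pattern_score` (isotopic pattern quality, 0 =
#'   perfect), `signal_measure` (signal-to-noise) and `dialect =
#'   "lacytools"`.
#' @export
read_lacytools <- function(path, alphabet = glycan_alphabet,
                           mode = "letter_digit") {
  lines <- readr::read_lines(path, progress = FALSE)
  blocks <- split_blocks(lines)
  if (length(blocks) == 0) {
    abort_glyco(sprintf("no blocks found in '%s'", path), "glycocurate_parse")
  }
  parsed <- lapply(blocks, parse_lacytools_block)
  charges <- vapply(parsed, `[[`, 0L, "charge")
  measures <- vapply(parsed, `[[`, "", "measure")

  records <- list()
  for (ch in sort(unique(charges))) {
    idx <- which(charges == ch)
    found <- measures[idx]
    missing <- setdiff(names(LACYTOOLS_MEASURES), found)
    if (length(missing) > 0) {
      abort_glyco(
        sprintf("charge %d+ lacks block(s): %s", ch,
                paste(LACYTOOLS_MEASURES[missing], collapse = "; ")),
        "glycocurate_structure"
      )
    }
    grp <- parsed[idx]
    names(grp) <- found
    ref <- grp[["intensity"]]
    for (ms in names(grp)) {
      b <- grp[[ms]]
      if (!identical(b$samples, ref$samples)) {
        abort_glyco(
          sprintf("block '%s' (charge %d+): sample rows differ from the intensity block",
                  LACYTOOLS_MEASURES[[ms]], ch),
          "glycocurate_structure"
        )
      }
      if (!identical(b$analytes, ref$analytes)) {
        abort_glyco(
          sprintf("block '%s' (charge %d+): analyte columns differ from the intensity block",
                  LACYTOOLS_MEASURES[[ms]], ch),
          "glycocurate_structure"
        )
      }
    }
    long <- tidyr::expand_grid(
      measurement_file = ref$samples,
      analyte = ref$analytes
    )
    long$charge <- ch
    for (ms in names(LACYTOOLS_MEASURES)) {
      long[[ms]] <- as.vector(t(grp[[ms]]$values))
    }
    records[[as.character(ch)]] <- long
  }
  out <- dplyr::bind_rows(records)
  info <- parse_analyte_names(unique(out$analyte), alphabet, mode)
  out <- dplyr::left_join(out, info, by = "analyte")
  out$dialect <- "lacytools"
  out$missing <- is.na(out$intensity)
  dup <- out[duplicated(out[c("measurement_file", "site", "glycan", "charge")]), ]
  if (nrow(dup) > 0) {
    abort_glyco(
      sprintf(paste0("duplicate composition(s) in LaCyTools input will lead ",
                     "to integration errors upstream: %s"),
              paste(unique(dup$analyte), collapse = ", ")),
      "glycocurate_duplicate_analyte"
    )
  }
  dplyr::select(
    out, "measurement_file", "analyte", "site", "glycan", "isomer_suffix",
    "charge", "intensity", "mass_error_ppm", "pattern_score",
    "signal_measure", "dialect", "missing"
  )
}

split_blocks <- function(lines) {
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  keep <- split(lines[!blank], grp[!blank])
  unname(keep[vapply(keep, length, 0L) > 0])
}

parse_lacytools_block <- function(block_lines) {
  header <- strsplit(block_lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    abort_glyco(
      sprintf("malformed block header: '%s'", block_lines[[1]]),
      "glycocurate_structure"
    )
  }
  measure_name <- trimws(header[[1]])
  measure <- names(LACYTOOLS_MEASURES)[match(measure_name, LACYTOOLS_MEASURES)]
  if (is.na(measure)) {
    abort_glyco(
      sprintf("unknown output type in block header: '%s'", measure_name),
      "glycocurate_structure"
    )
  }
  charge_txt <- trimws(header[[2]])
  if (!grepl("^charge [0-9]+\\+$", charge_txt)) {
    abort_glyco(
      sprintf("malformed charge field in block header: '%s'", charge_txt),
      "glycocurate_structure"
    )
  }
  charge <- as.integer(sub("^charge ([0-9]+)\\+$", "\\1", charge_txt))
  if (length(block_lines) < 3) {
    abort_glyco(
      sprintf("block '%s' (charge %d+) has no data rows", measure_name, charge),
      "glycocurate_structure"
    )
  }
  cols <- strsplit(block_lines[[2]], "\t", fixed = TRUE)[[1]]
  analytes <- cols[-1]
  rows <- strsplit(block_lines[-(1:2)], "\t", fixed = TRUE)
  samples <- vapply(rows, `[[`, "", 1L)
  values <- matrix(NA_real_, nrow = length(samples), ncol = length(analytes))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1]
    length(cells) <- length(analytes)  # right-pad short rows with NA
    cells[!nzchar(trimws(cells))] <- NA_character_
    values[i, ] <- suppressWarnings(as.numeric(cells))
  }
  list(measure = measure, charge = charge, samples = samples,
       analytes = analytes, values = values)
}
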