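#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_glyco <- function(msg, class) {
  rlang::abort(msg, class = c(class, "glycocurate_error"))
}

# 96-well geometry is the only supported plate layout.
WELL_ROWS <- LETTERS[1:8]
WELL_COLS <- 1:12

is_valid_well <- function(well) {
  grepl("^[A-H](1[0-2]|[1-9])$", well)
}

# "plate<k>_<well>" position token embedded in measurement file names.
PLATE_POSITION_REGEX <- "(plate[0-9]+)_([A-H](?:1[0-2]|[1-9]))"

extract_plate_position <- function(x) {
  m <- regexpr(PLATE_POSITION_REGEX, x)
  out <- rep(NA_character_, length(x))
  hit <- m > 0
  out[hit] <- regmatches(x, m)[seq_len(sum(hit))]
  out
}

split_plate_position <- function(pos) {
  plate <- sub("_.*$", "", pos)
  well <- sub("^[^_]*_", "", pos)
  list(plate = plate, well = well)
}

# Recursively remove NULL entries so settings survive a JSON round-trip
# (absent keys fall back to the same defaults on replay).
drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, TRUE)]
  lapply(x, drop_nulls)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_glyco(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "glycocurate_missing_column"
    )
  }
  invisible(df)
}

# Read a small tabular input that may be CSV, TSV or XLSX.
read_table_any <- function(path, what = "input table") {
  if (is.data.frame(path)) {
    return(tibble::as_tibble(path))
  }
  if (!file.exists(path)) {
    abort_glyco(sprintf("%s not found: %s", what, path), "glycocurate_io")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort_glyco("reading XLSX requires the 'readxl' package; supply CSV instead",
                  "glycocurate_io")
    }
    return(tibble::as_tibble(readxl::read_excel(path)))
  }
  delim <- if (ext == "tsv" || ext == "txt") "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}
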