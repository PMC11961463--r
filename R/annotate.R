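#' Rename isomeric glycan compositions with running lowercase letters
#'
#' In Skyline reports, a glycan composition appearing multiple times on the
#' same glycosylation site (and charge state) is assumed to represent
#' chromatographically separated isomers. Duplicates receive running
#' lowercase suffixes `a`, `b`, `c`, ... in order of appearance in the
#' report, so that — provided retention order is conserved across samples —
#' the same isomer always gets the same letter. Unique compositions are left
#' untouched and the operation is idempotent. Duplicate compositions in
#' LaCyTools input are rejected: there they indicate an upstream targeting
#' error ("duplicate composition will lead to integration errors").
#'
#' @param records Analyte-record tibble from [read_skyline()] (must carry
#'   `source_row`).
#' @return The records with `glycan`, `analyte` and `isomer_suffix` updated.
#' @export
rename_isomers <- function(records) {
  if (any(records$dialect == "lacytools")) {
    dup <- records[duplicated(records[c("measurement_file", "site", "glycan",
                                        "charge")]), ]
    if (nrow(dup) > 0) {
      abort_glyco(
        "duplicate compositions in LaCyTools input indicate upstream integration errors",
        "glycocurate_duplicate_analyte"
      )
    }
    return(records)
  }
  if (!"source_row" %in% names(records)) {
    abort_glyco("rename_isomers() needs the 'source_row' column from read_skyline()",
                "glycocurate_missing_column")
  }
  # one entity per source row; duplicates counted within (site, glycan, charge)
  entities <- dplyr::distinct(
    records, .data$site, .data$glycan, .data$charge, .data$source_row
  )
  entities <- dplyr::arrange(entities, .data$source_row)
  entities <- dplyr::group_by(entities, .data$site, .data$glycan, .data$charge)
  entities <- dplyr::mutate(
    entities,
    .n_dup = dplyr::n(),
    .rank = dplyr::row_number(),
    new_glycan = ifelse(.data$.n_dup > 1L,
                        paste0(.data$glycan, letters[.data$.rank]),
                        .data$glycan)
  )
  entities <- dplyr::ungroup(entities)
  if (any(entities$.n_dup > length(letters))) {
    abort_glyco("more than 26 isomers of one composition are not supported",
                "glycocurate_parse")
  }
  map <- entities[c("source_row", "new_glycan")]
  out <- dplyr::left_join(records, map, by = "source_row")
  out$glycan <- out$new_glycan
  out$analyte <- paste0(out$site, out$glycan)
  out$isomer_suffix <- ifelse(grepl("[a-z]$", out$glycan),
                              substr(out$glycan, nchar(out$glycan),
                                     nchar(out$glycan)),
                              NA_character_)
  out$new_glycan <- NULL
  out
}

#' Link measurement file names to sample IDs via a plate layout
#'
#' Measurement file names are expected to embed a plate position token such
#' as `"plate1_C10"`. The layout table maps those positions to sample IDs.
#' Only the 96-well geometry (rows A-H, columns 1-12) is supported; other
#' well labels are rejected. Unresolved measurement files are kept (with
#' `sample_id = NA`) and reported in the `"unresolved"` attribute rather
#' than dropped silently.
#'
#' @param records Analyte-record tibble.
#' @param layout A data frame, CSV or XLSX path with columns
#'   `plate_position` (e.g. `"plate1_C10"`) and `sample_id`.
#' @return Records with `sample_id`, `plate` and `well` columns filled;
#'   attribute `"unresolved"` lists measurement files without a layout entry.
#' @export
link_plate_layout <- function(records, layout) {
  layout <- read_table_any(layout, "plate layout")
  assert_columns(layout, c("plate_position", "sample_id"), "plate layout")
  pos <- split_plate_position(layout$plate_position)
  bad_well <- !is_valid_well(pos$well) | !grepl("^plate[0-9]+$", pos$plate)
  if (any(bad_well)) {
    abort_glyco(
      sprintf("plate layout positions outside the 96-well geometry (A-H x 1-12): %s",
              paste(layout$plate_position[bad_well], collapse = ", ")),
      "glycocurate_layout"
    )
  }
  if (anyDuplicated(layout$plate_position)) {
    dup <- unique(layout$plate_position[duplicated(layout$plate_position)])
    abort_glyco(
      sprintf("duplicate well assignment(s) in plate layout: %s",
              paste(dup, collapse = ", ")),
      "glycocurate_layout"
    )
  }
  token <- extract_plate_position(records$measurement_file)
  m <- match(token, layout$plate_position)
  records$sample_id <- layout$sample_id[m]
  parts <- split_plate_position(ifelse(is.na(token), "", token))
  records$plate <- ifelse(is.na(token), NA_character_, parts$plate)
  records$well <- ifelse(is.na(token), NA_character_, parts$well)
  unresolved <- unique(records$measurement_file[is.na(records$sample_id)])
  if (length(unresolved) > 0) {
    rlang::warn(
      sprintf("%d measurement file(s) could not be resolved to a sample ID: %s",
              length(unresolved), paste(unresolved, collapse = ", ")),
      class = "glycocurate_unresolved"
    )
  }
  attr(records, "unresolved") <- unresolved
  records
}

#' Default sample-type extraction rules
#'
#' Ordered regex-to-type rules applied to sample IDs; the first match wins.
#' @export
default_sample_type_rules <- c(
  "^(?i)pool" = "pool",
  "^(?i)blank" = "blank",
  "^(?i)(neg|nc\\b)" = "negative_control",
  "^(?i)(sample|patient|pt)" = "sample"
)

#' Infer sample types from sample IDs
#'
#' Applies ordered regex rules to each sample ID (first matching rule wins);
#' an explicit mapping table, when given, overrides the regex result for the
#' IDs it lists. IDs matching no rule are typed `"unknown"` and reported.
#'
#' @param sample_ids Character vector of sample IDs.
#' @param rules Named character vector `c(regex = type, ...)`, in priority
#'   order.
#' @param mapping Optional data frame / CSV / XLSX with columns `sample_id`,
#'   `sample_type`; IDs listed here take precedence. Mapping IDs absent from
#'   `sample_ids` trigger a warning.
#' @return Tibble with `sample_id` and `sample_type` (one row per unique ID).
#' @export
infer_sample_types <- function(sample_ids, rules = default_sample_type_rules,
                               mapping = NULL) {
  ids <- unique(sample_ids[!is.na(sample_ids)])
  type <- rep("unknown", length(ids))
  matched <- rep(FALSE, length(ids))
  for (i in seq_along(rules)) {
    hit <- !matched & grepl(names(rules)[[i]], ids, perl = TRUE)
    type[hit] <- rules[[i]]
    matched <- matched | hit
  }
  if (!is.null(mapping)) {
    mapping <- read_table_any(mapping, "sample-type mapping")
    assert_columns(mapping, c("sample_id", "sample_type"), "sample-type mapping")
    absent <- setdiff(mapping$sample_id, ids)
    if (length(absent) > 0) {
      rlang::warn(
        sprintf("sample-type mapping lists ID(s) absent from the data: %s",
                paste(absent, collapse = ", ")),
        class = "glycocurate_mapping_absent"
      )
    }
    m <- match(ids, mapping$sample_id)
    type[!is.na(m)] <- mapping$sample_type[m[!is.na(m)]]
    matched[!is.na(m)] <- TRUE
  }
  if (any(!matched)) {
    rlang::warn(
      sprintf("sample ID(s) with no matching type rule, typed 'unknown': %s",
              paste(ids[!matched], collapse = ", ")),
      class = "glycocurate_unknown_type"
    )
  }
  tibble::tibble(sample_id = ids, sample_type = type)
}

#' Merge a metadata table into the record table
#'
#' Left join on `sample_id`: every record row is kept, metadata columns are
#' appended. Metadata sample IDs must be unique (no row multiplication).
#' Sample IDs present only in the metadata, and data sample IDs without
#' metadata, are reported in attributes `"metadata_only"` and `"data_only"`.
#'
#' @param records Analyte-record tibble with `sample_id`.
#' @param metadata Data frame / CSV / XLSX with a `sample_id` column.
#' @return Records with metadata columns joined.
#' @export
merge_metadata <- function(records, metadata) {
  metadata <- read_table_any(metadata, "metadata")
  if (nrow(metadata) == 0 || ncol(metadata) == 0) {
    attr(records, "metadata_only") <- character()
    attr(records, "data_only") <- unique(records$sample_id)
    return(records)
  }
  assert_columns(metadata, "sample_id", "metadata")
  if (anyDuplicated(metadata$sample_id)) {
    dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
    abort_glyco(
      sprintf("duplicate sample_id(s) in metadata: %s",
              paste(dup, collapse = ", ")),
      "glycocurate_metadata"
    )
  }
  out <- dplyr::left_join(records, metadata, by = "sample_id",
                          suffix = c("", ".meta"))
  attr(out, "metadata_only") <- setdiff(metadata$sample_id, records$sample_id)
  attr(out, "data_only") <- setdiff(unique(records$sample_id),
                                    metadata$sample_id)
  out
}
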