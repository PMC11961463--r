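#' Default monosaccharide alphabet
#'
#' Single-letter codes for the monosaccharide residues recognised in glycan
#' composition labels: H (hexose), N (N-acetylhexosamine), F (fucose),
#' S (N-acetylneuraminic acid) and G (glycolylneuraminic acid).
#' @export
glycan_alphabet <- c("H", "N", "F", "S", "G")

#' Parse a glycan composition label
#'
#' A composition label is a sequence of `<letter><count>` tokens, e.g.
#' `"H5N4F1S1"`, optionally followed by a single lowercase isomer suffix
#' (`"N1a"`). Letters must come from `alphabet` and counts are positive
#' integers.
#'
#' @param label Character scalar, the composition part of an analyte name.
#' @param alphabet Character vector of allowed monosaccharide letters.
#' @return A list with `counts` (named integer vector in first-appearance
#'   order) and `isomer_suffix` (`NA` or a lowercase letter).
#' @export
parse_composition <- function(label, alphabet = glycan_alphabet) {
  stopifnot(is.character(label), length(label) == 1L)
  suffix <- NA_character_
  body <- label
  if (grepl("[a-z]$", body)) {
    suffix <- substr(body, nchar(body), nchar(body))
    body <- substr(body, 1L, nchar(body) - 1L)
  }
  token_re <- sprintf("[%s][0-9]+", paste(alphabet, collapse = ""))
  tokens <- regmatches(body, gregexpr(token_re, body))[[1]]
  consumed <- paste(tokens, collapse = "")
  if (!nzchar(body) || !identical(consumed, body)) {
    bad <- sub(paste0("^(", token_re, ")*"), "", body)
    abort_glyco(
      sprintf("cannot parse composition '%s': offending substring '%s'",
              label, bad),
      "glycocurate_parse"
    )
  }
  letters_ <- substr(tokens, 1L, 1L)
  if (anyDuplicated(letters_)) {
    abort_glyco(
      sprintf("composition '%s' repeats monosaccharide letter(s): %s", label,
              paste(unique(letters_[duplicated(letters_)]), collapse = ", ")),
      "glycocurate_parse"
    )
  }
  counts <- as.integer(substring(tokens, 2L))
  names(counts) <- letters_
  list(counts = counts, isomer_suffix = suffix)
}

#' Serialise monosaccharide counts back to a composition label
#'
#' Inverse of [parse_composition()]: letters are emitted in the order of the
#' `counts` vector, so round-tripping a parsed label reproduces it (minus any
#' isomer suffix).
#'
#' @param counts Named integer vector of residue counts.
#' @return Character scalar.
#' @export
serialize_composition <- function(counts) {
  paste0(names(counts), counts, collapse = "")
}

#' Split an analyte name into glycosylation site and glycan composition
#'
#' Analyte names follow the `"<site><composition>"` convention, e.g.
#' `"IgGI1H4N4F1"` where `"IgGI1"` identifies the glycosylation site (the
#' tryptic peptide carrying it) and `"H4N4F1"` is the glycan composition.
#' The default split rule places the boundary before the first
#' `<alphabet-letter><digit>` token, which handles site names that themselves
#' contain digits (`"peptide1H5N4F1S1"` splits into `"peptide1"` +
#' `"H5N4F1S1"`). The alternative `mode = "first_digit"` ends the site
#' before the first digit anywhere in the name; digits between the site and
#' the first composition letter are treated as part of neither (so
#' `"IgGI1H4N4F1"` yields site `"IgGI"` and composition `"H4N4F1"`).
#'
#' @param label Character scalar, the full analyte name.
#' @param alphabet Allowed monosaccharide letters.
#' @param mode `"letter_digit"` (default) or `"first_digit"`.
#' @return A list with `site`, `glycan` (composition label including any
#'   isomer suffix), `counts` and `isomer_suffix`.
#' @export
split_analyte_name <- function(label, alphabet = glycan_alphabet,
                               mode = c("letter_digit", "first_digit")) {
  mode <- match.arg(mode)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (mode == "letter_digit") {
    token_re <- sprintf("[%s][0-9]", paste(alphabet, collapse = ""))
    m <- regexpr(token_re, label)
    if (m < 0) {
      abort_glyco(
        sprintf("analyte name '%s' contains no composition token", label),
        "glycocurate_parse"
      )
    }
    site <- substr(label, 1L, m - 1L)
    glycan <- substr(label, m, nchar(label))
  } else {
    m <- regexpr("[0-9]", label)
    if (m < 0) {
      abort_glyco(
        sprintf("analyte name '%s' contains no digit", label),
        "glycocurate_parse"
      )
    }
    site <- substr(label, 1L, m - 1L)
    glycan <- sub("^[0-9]+", "", substr(label, m, nchar(label)))
  }
  comp <- parse_composition(glycan, alphabet)
  list(site = site, glycan = glycan, counts = comp$counts,
       isomer_suffix = comp$isomer_suffix)
}

# Vectorised convenience used by the readers.
parse_analyte_names <- function(labels, alphabet = glycan_alphabet,
                                mode = "letter_digit") {
  parsed <- lapply(labels, split_analyte_name, alphabet = alphabet, mode = mode)
  tibble::tibble(
    analyte = labels,
    site = vapply(parsed, `[[`, "", "site"),
    glycan = vapply(parsed, `[[`, "", "glycan"),
    isomer_suffix = vapply(parsed, `[[`, "", "isomer_suffix")
  )
}
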