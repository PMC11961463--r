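## Glycosylation-trait formula mini-language.
##
## Space-tokenized grammar:
##   formula := sum [ "/" sum ]
##   sum     := term { "+" term }
##   term    := [ number "*" ] analyte-name
## "/" binds last and may occur at most once; there are no parentheses.
## Analyte names are full names (site prefix + composition), and traits over
## relative abundances are themselves percentages: a ratio trait evaluates
## to 100 * numerator / denominator.

#' Parse a single glycosylation-trait formula
#'
#' @param text Formula string, tokens separated by spaces, e.g.
#'   `"IgGI1H3N4 + 0.5 * IgGI1H4N4"` or `"A / A + B"`.
#' @param name Trait name (no spaces allowed).
#' @return A `trait_formula`: list with `name`, `numerator` and optional
#'   `denominator`, each a tibble (`coefficient`, `analyte`).
#' @export
parse_trait_formula <- function(text, name = "trait") {
  if (grepl("[[:space:]]", name)) {
    abort_glyco(sprintf("trait name '%s' contains spaces", name),
                "glycocurate_trait_parse")
  }
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  if (length(tokens) == 0 || !nzchar(tokens[1])) {
    abort_glyco(sprintf("trait '%s': empty formula", name),
                "glycocurate_trait_parse")
  }
  slash_at <- which(tokens == "/")
  if (length(slash_at) > 1) {
    abort_glyco(
      sprintf("trait '%s': more than one '/' (at tokens %s)", name,
              paste(slash_at, collapse = ", ")),
      "glycocurate_trait_parse"
    )
  }
  parse_sum <- function(toks, offset) {
    terms <- list()
    i <- 1L
    repeat {
      if (i > length(toks)) {
        abort_glyco(
          sprintf("trait '%s': expected a term at token %d", name, offset + i),
          "glycocurate_trait_parse"
        )
      }
      tok <- toks[i]
      coef <- 1
      is_num <- !is.na(suppressWarnings(as.numeric(tok)))
      if (is_num) {
        if (i + 1L > length(toks) || toks[i + 1L] != "*") {
          abort_glyco(
            sprintf("trait '%s': number '%s' at token %d must be followed by '*'",
                    name, tok, offset + i),
            "glycocurate_trait_parse"
          )
        }
        coef <- as.numeric(tok)
        i <- i + 2L
        if (i > length(toks)) {
          abort_glyco(
            sprintf("trait '%s': dangling '*' at token %d", name, offset + i - 1L),
            "glycocurate_trait_parse"
          )
        }
        tok <- toks[i]
      }
      if (tok %in% c("+", "*", "/")) {
        abort_glyco(
          sprintf("trait '%s': unexpected operator '%s' at token %d", name,
                  tok, offset + i),
          "glycocurate_trait_parse"
        )
      }
      terms[[length(terms) + 1L]] <- list(coefficient = coef, analyte = tok)
      i <- i + 1L
      if (i > length(toks)) break
      if (toks[i] != "+") {
        abort_glyco(
          sprintf("trait '%s': expected '+' at token %d, got '%s'", name,
                  offset + i, toks[i]),
          "glycocurate_trait_parse"
        )
      }
      i <- i + 1L
    }
    tibble::tibble(
      coefficient = vapply(terms, `[[`, 0, "coefficient"),
      analyte = vapply(terms, `[[`, "", "analyte")
    )
  }
  if (length(slash_at) == 1) {
    numerator <- parse_sum(tokens[seq_len(slash_at - 1L)], 0L)
    denominator <- parse_sum(tokens[-seq_len(slash_at)], slash_at)
  } else {
    numerator <- parse_sum(tokens, 0L)
    denominator <- NULL
  }
  structure(list(name = name, numerator = numerator,
                 denominator = denominator),
            class = "trait_formula")
}

#' Serialise a trait formula back to its textual syntax
#'
#' Inverse of [parse_trait_formula()]; re-parsing the output yields an
#' identical expression tree.
#'
#' @param formula A `trait_formula`.
#' @return Character scalar in the space-tokenized syntax.
#' @export
format_trait_formula <- function(formula) {
  fmt_sum <- function(tbl) {
    paste(ifelse(tbl$coefficient == 1, tbl$analyte,
                 paste(format(tbl$coefficient, trim = TRUE), "*",
                       tbl$analyte)),
          collapse = " + ")
  }
  out <- fmt_sum(formula$numerator)
  if (!is.null(formula$denominator)) {
    out <- paste(out, "/", fmt_sum(formula$denominator))
  }
  out
}

#' @export
print.trait_formula <- function(x, ...) {
  cat(sprintf("<trait> %s = %s\n", x$name, format_trait_formula(x)))
  invisible(x)
}

#' Read a trait-formula workbook
#'
#' The workbook (XLSX or CSV) must contain exactly the two columns `trait`
#' and `formula`; each row defines one glycosylation trait in the
#' space-tokenized formula syntax.
#'
#' @param x Path to the workbook, or a data frame with those columns.
#' @return A named list of `trait_formula` objects.
#' @export
parse_trait_formulas <- function(x) {
  tbl <- read_table_any(x, "trait workbook")
  assert_columns(tbl, c("trait", "formula"), "trait workbook")
  if (anyDuplicated(tbl$trait)) {
    abort_glyco(
      sprintf("duplicate trait name(s): %s",
              paste(unique(tbl$trait[duplicated(tbl$trait)]), collapse = ", ")),
      "glycocurate_trait_parse"
    )
  }
  out <- Map(parse_trait_formula, tbl$formula, tbl$trait)
  names(out) <- tbl$trait
  out
}

#' Write trait formulas to a CSV workbook
#'
#' @param formulas Named list of `trait_formula` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_formulas <- function(formulas, path) {
  tbl <- tibble::tibble(
    trait = vapply(formulas, `[[`, "", "name"),
    formula = vapply(formulas, format_trait_formula, "")
  )
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Illustrative IgG Fc N-glycosylation trait formulas
#'
#' Returns the path to the example trait workbook shipped with the package:
#' fucosylation, bisection, galactosylation per antenna and sialylation per
#' antenna over common diantennary IgG1 Fc compositions. The set is
#' illustrative configuration for the formula syntax — adapt the analyte
#' names and compositions to the dataset at hand.
#'
#' @return Path to the example CSV.
#' @export
example_trait_formulas <- function() {
  system.file("extdata", "igg_traits_example.csv", package = "glycocurate",
              mustWork = TRUE)
}

#' Compute glycosylation traits from relative abundances
#'
#' Evaluates each formula per sample over the analyte relative-abundance
#' map. Formula analytes absent from the dataset are ignored (dropped from
#' both numerator and denominator); dataset analytes covered by no formula
#' trigger a warning listing them (attribute `"uncovered_analytes"`).
#' Sum-type traits evaluate to the weighted sum of abundances (already in
#' percent); ratio-type traits to `100 * numerator / denominator`, missing
#' when the denominator is 0. A formula whose terms are all absent yields a
#' missing trait value with a warning.
#'
#' @param rel_abund Relative-abundance table from [normalize_total_area()].
#' @param formulas Named list of `trait_formula` objects.
#' @param missing_analytes `"drop"` (default; matches "compositions not
#'   present are ignored") or `"zero"` (treat absent analytes as 0% — same
#'   sums, but ratio denominators keep the term).
#' @return Tibble with `sample_id` and one column per trait.
#' @export
compute_traits <- function(rel_abund, formulas,
                           missing_analytes = c("drop", "zero")) {
  missing_analytes <- match.arg(missing_analytes)
  assert_columns(rel_abund, c("sample_id", "analyte", "relative_abundance"),
                 "relative-abundance table")
  known <- unique(rel_abund$analyte)
  used <- unique(unlist(lapply(formulas, function(f) {
    c(f$numerator$analyte,
      if (!is.null(f$denominator)) f$denominator$analyte)
  })))
  uncovered <- setdiff(known, used)
  if (length(uncovered) > 0 && length(formulas) > 0) {
    rlang::warn(
      sprintf("analyte(s) not covered by any trait formula: %s",
              paste(uncovered, collapse = ", ")),
      class = "glycocurate_uncovered_analytes"
    )
  }
  all_absent <- vapply(formulas, function(f) {
    !any(f$numerator$analyte %in% known) &&
      (is.null(f$denominator) || !any(f$denominator$analyte %in% known))
  }, TRUE)
  if (any(all_absent)) {
    rlang::warn(
      sprintf("trait(s) referencing only absent analytes, reported missing: %s",
              paste(names(formulas)[all_absent], collapse = ", ")),
      class = "glycocurate_absent_trait"
    )
  }

  wide <- tidyr::pivot_wider(
    rel_abund[c("sample_id", "analyte", "relative_abundance")],
    names_from = "analyte", values_from = "relative_abundance"
  )
  eval_sum <- function(tbl, row) {
    if (missing_analytes == "drop") {
      tbl <- tbl[tbl$analyte %in% known, ]
    }
    if (nrow(tbl) == 0) return(NA_real_)
    vals <- vapply(tbl$analyte, function(a) {
      if (a %in% names(row)) row[[a]] else 0
    }, 0)
    sum(tbl$coefficient * vals)
  }
  out <- tibble::tibble(sample_id = wide$sample_id)
  for (f in formulas) {
    vals <- vapply(seq_len(nrow(wide)), function(i) {
      row <- wide[i, ]
      num <- eval_sum(f$numerator, row)
      if (is.null(f$denominator)) return(num)
      den <- eval_sum(f$denominator, row)
      if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
      100 * num / den
    }, 0)
    out[[f$name]] <- vals
  }
  attr(out, "uncovered_analytes") <- uncovered
  out
}
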