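# Fixture builders shared across the test files. Everything is generated
# in code; nothing is read from disk except what the tests write themselves.

# Minimal analyte-record constructor with sensible defaults.
make_records <- function(sample_id, site = "IgGI1", glycan = "H3N4",
                         charge = 2L, intensity = 100,
                         mass_error_ppm = 0, pattern_score = 0,
                         signal_measure = 100, dialect = "lacytools",
                         sample_type = "sample", ...) {
  tibble::tibble(
    sample_id = sample_id, site = site, glycan = glycan,
    charge = as.integer(charge), intensity = intensity,
    mass_error_ppm = mass_error_ppm, pattern_score = pattern_score,
    signal_measure = signal_measure, dialect = dialect,
    sample_type = sample_type,
    analyte = paste0(site, glycan),
    isomer_suffix = NA_character_,
    measurement_file = sample_id,
    missing = is.na(intensity),
    ...
  )
}

# Small hand-written LaCyTools summary file: values is a named list
# measure -> list(charge -> matrix[sample, analyte]).
write_lacytools_fixture <- function(path, samples, analytes, values) {
  measure_names <- c(
    intensity = "Analyte Intensity (Background Subtracted)",
    mass_error_ppm = "Mass Accuracy [ppm]",
    pattern_score = "Isotopic Pattern Quality",
    signal_measure = "S/N"
  )
  lines <- character(0)
  for (ch in names(values[[1]])) {
    for (ms in names(measure_names)) {
      m <- values[[ms]][[ch]]
      lines <- c(
        lines,
        paste0(measure_names[[ms]], "\tcharge ", ch, "+"),
        paste0("\t", paste(analytes, collapse = "\t")),
        vapply(seq_along(samples), function(i) {
          cells <- ifelse(is.na(m[i, ]), "",
                          format(m[i, ], trim = TRUE, scientific = FALSE))
          paste(c(samples[i], cells), collapse = "\t")
        }, ""),
        ""
      )
    }
  }
  readr::write_lines(lines, path)
  path
}

# Small Skyline report CSV from a long tibble with columns
# site, glycan, charge, sample, idotp, mass, area; an optional `src` column
# identifies report rows (needed to express duplicate/isomer rows).
write_skyline_fixture <- function(path, long) {
  if (!"src" %in% names(long)) {
    long$src <- as.integer(factor(paste(long$site, long$glycan, long$charge),
                                  levels = unique(paste(long$site,
                                                        long$glycan,
                                                        long$charge))))
  }
  key <- unique(long[c("src", "site", "glycan", "charge")])
  key <- key[order(key$src), ]
  out <- tibble::tibble(
    `Protein name` = key$site, Peptide = key$glycan,
    `Precursor Charge` = key$charge
  )
  for (s in unique(long$sample)) {
    sub <- long[long$sample == s, ]
    m <- match(key$src, sub$src)
    out[[paste(s, "Isotope Dot Product")]] <- sub$idotp[m]
    out[[paste(s, "Average mass error PPM")]] <- sub$mass[m]
    out[[paste(s, "Total area MS1")]] <- sub$area[m]
  }
  readr::write_csv(out, path)
  path
}

# Reduced simulated study for fast tests.
tiny_spec <- function(seed = 11, ...) {
  simulation_spec(
    seed = seed, n_samples = 30, n_pools = 4, n_negative_controls = 4,
    sites = "IgGI1",
    compositions = c("H3N4", "H4N4F1", "H5N4", "H3N5F1", "H5N4F1S1"),
    charges = 2L,
    ...
  )
}

# Independent brute-force re-evaluation of the quality rules, written as a
# plain per-record loop (deliberately not sharing code with the package).
brute_force_flags <- function(records, criteria) {
  n <- nrow(records)
  out <- logical(n)
  for (i in seq_len(n)) {
    me <- records$mass_error_ppm[i]
    ps <- records$pattern_score[i]
    sg <- records$signal_measure[i]
    it <- records$intensity[i]
    mass_ok <- !is.na(me) && me >= criteria$mass_error_window[1] &&
      me <= criteria$mass_error_window[2]
    if (criteria$dialect == "lacytools") {
      pat_ok <- !is.na(ps) && ps <= criteria$pattern_threshold
      sig_ok <- !is.na(sg) && sg >= criteria$signal_threshold
    } else {
      pat_ok <- !is.na(ps) && ps >= criteria$pattern_threshold
      sig_ok <- !is.na(sg) && sg > criteria$signal_threshold
    }
    out[i] <- mass_ok && pat_ok && sig_ok && !is.na(it)
  }
  out
}

# Randomized record table that deliberately includes boundary values.
random_quality_records <- function(n, dialect, seed) {
  set.seed(seed)
  if (dialect == "lacytools") {
    mass <- sample(c(stats::runif(n, -40, 40), -20, 20, -20.0001, 20.0001),
                   n)
    pattern <- sample(c(stats::runif(n, 0, 0.5), 0.2, 0.2000001), n)
    signal <- sample(c(stats::runif(n, 0, 30), 9, 8.9999), n)
  } else {
    mass <- sample(c(stats::runif(n, -5, 5), -2, 2), n)
    pattern <- sample(c(stats::runif(n, 0.5, 1), 0.9, 0.8999999), n)
    signal <- sample(c(stats::runif(n, 0, 10), 0, 1e-12), n)
  }
  intensity <- stats::runif(n, 0, 1000)
  intensity[sample.int(n, max(1, n %/% 50))] <- NA
  make_records(
    sample_id = sprintf("s%05d", seq_len(n)),
    intensity = intensity, mass_error_ppm = mass, pattern_score = pattern,
    signal_measure = signal, dialect = dialect
  )
}

# Second, independent interpreter for the trait-formula syntax: regex/split
# based, evaluating on a named abundance vector.
interpret_trait_independently <- function(text, abund) {
  halves <- strsplit(text, " / ", fixed = TRUE)[[1]]
  eval_half <- function(h) {
    terms <- strsplit(h, " + ", fixed = TRUE)[[1]]
    total <- 0
    any_present <- FALSE
    for (t in terms) {
      bits <- strsplit(t, " * ", fixed = TRUE)[[1]]
      if (length(bits) == 2) {
        coef <- as.numeric(bits[1]); name <- bits[2]
      } else {
        coef <- 1; name <- bits[1]
      }
      if (name %in% names(abund)) {
        total <- total + coef * abund[[name]]
        any_present <- TRUE
      }
    }
    if (!any_present) return(NA_real_)
    total
  }
  num <- eval_half(halves[1])
  if (length(halves) == 1) return(num)
  den <- eval_half(halves[2])
  if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
  100 * num / den
}

# Random well-formed formula over a pool of analyte names.
random_formula_text <- function(pool, ratio = FALSE) {
  pick_sum <- function() {
    k <- sample(1:4, 1)
    terms <- vapply(sample(pool, k), function(a) {
      if (stats::runif(1) < 0.5) {
        paste(format(round(stats::runif(1, 0.1, 2), 2), trim = TRUE), "*", a)
      } else {
        a
      }
    }, "")
    paste(terms, collapse = " + ")
  }
  if (ratio) paste(pick_sum(), "/", pick_sum()) else pick_sum()
}
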