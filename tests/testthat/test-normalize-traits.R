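test_that("total-area normalization gives percentages per site", {
  rec <- make_records("s1", glycan = c("H1N1", "H2N1"),
                      intensity = c(60, 40))
  ra <- normalize_total_area(rec)
  expect_equal(sort(ra$relative_abundance), c(40, 60))
})

test_that("a single analyte normalizes to exactly 100%", {
  rec <- make_records("s1", glycan = "H1N1", intensity = 123.4)
  expect_equal(normalize_total_area(rec)$relative_abundance, 100)
})

test_that("retained charge states are summed before normalization", {
  rec <- make_records("s1", glycan = c("H1N1", "H1N1", "H2N1"),
                      charge = c(2L, 3L, 2L), intensity = c(30, 30, 40))
  ra <- normalize_total_area(rec)
  expect_equal(nrow(ra), 2)
  expect_equal(ra$relative_abundance[ra$glycan == "H1N1"], 60)
})

test_that("sites are normalized independently and sums hit 100", {
  set.seed(71)
  rec <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:10), function(s) {
    make_records(s, site = rep(c("A1", "B1"), each = 4),
                 glycan = rep(sprintf("H%dN1", 1:4), 2),
                 intensity = stats::rlnorm(8, 5, 1))
  }))
  ra <- normalize_total_area(rec)
  sums <- dplyr::summarise(dplyr::group_by(ra, .data$sample_id, .data$site),
                           s = sum(.data$relative_abundance),
                           .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9))
  # independent arithmetic for one cell
  x <- rec[rec$sample_id == "s01" & rec$site == "A1", ]
  expect_equal(
    ra$relative_abundance[ra$sample_id == "s01" & ra$site == "A1" &
                            ra$glycan == "H2N1"],
    100 * x$intensity[x$glycan == "H2N1"] / sum(x$intensity)
  )
})

test_that("zero totals yield missing values and negatives are rejected", {
  rec <- make_records("s1", glycan = c("H1N1", "H2N1"), intensity = 0)
  expect_true(all(is.na(normalize_total_area(rec)$relative_abundance)))
  rec$intensity <- c(-1, 5)
  expect_error(normalize_total_area(rec), class = "glycocurate_normalize")
})

test_that("formula parsing matches the worked syntax examples", {
  f <- parse_trait_formula("IgGI1H3N4 + 0.5 * IgGI1H4N4", "gal")
  expect_equal(f$numerator$coefficient, c(1, 0.5))
  expect_equal(f$numerator$analyte, c("IgGI1H3N4", "IgGI1H4N4"))
  expect_null(f$denominator)

  r <- parse_trait_formula("A / A + B", "ratio")
  expect_equal(r$numerator$analyte, "A")
  expect_equal(r$denominator$analyte, c("A", "B"))
  expect_equal(r$denominator$coefficient, c(1, 1))
})

test_that("malformed formulas report the offending token position", {
  err <- expect_error(parse_trait_formula("A + * B", "t"),
                      class = "glycocurate_trait_parse")
  expect_match(conditionMessage(err), "token 3")
  expect_error(parse_trait_formula("A / B / C", "t"),
               class = "glycocurate_trait_parse")
  expect_error(parse_trait_formula("2 * ", "t"),
               class = "glycocurate_trait_parse")
  expect_error(parse_trait_formula("A + B", "bad name"),
               class = "glycocurate_trait_parse")
})

test_that("serialise-then-reparse yields an identical tree", {
  texts <- c("A", "0.5 * A + B", "A + 2 * B / C + 0.25 * D",
             "IgGI1H5N4F1 + IgGI1H5N4F1S1 / IgGI1H5N4 + IgGI1H5N4F1")
  for (tx in texts) {
    f <- parse_trait_formula(tx, "t")
    f2 <- parse_trait_formula(format_trait_formula(f), "t")
    expect_identical(f, f2)
  }
})

test_that("trait evaluation reproduces the worked micro-examples", {
  ra <- tibble::tibble(sample_id = "s1", site = "X1",
                       glycan = c("A", "B", "C"),
                       analyte = c("A", "B", "C"),
                       relative_abundance = c(50, 30, 20))
  f1 <- parse_trait_formula("A + 0.5 * B", "sum_trait")
  f2 <- parse_trait_formula("A / A + B", "ratio_trait")
  out <- suppressWarnings(
    compute_traits(ra, list(sum_trait = f1, ratio_trait = f2))
  )
  expect_equal(out$sum_trait, 65)
  expect_equal(out$ratio_trait, 62.5)
})

test_that("absent analytes are dropped and uncovered analytes warned about", {
  ra <- tibble::tibble(sample_id = "s1", site = "X1",
                       glycan = c("A", "B"), analyte = c("A", "B"),
                       relative_abundance = c(70, 30))
  f <- parse_trait_formula("A + GHOST", "t")
  expect_warning(out <- compute_traits(ra, list(t = f)),
                 class = "glycocurate_uncovered_analytes")
  expect_equal(out$t, 70)

  all_absent <- parse_trait_formula("GHOST1 + GHOST2", "gone")
  w <- capture_warnings(out2 <- compute_traits(ra, list(gone = all_absent)))
  expect_true(is.na(out2$gone))
})

test_that("zero denominators yield missing trait values", {
  ra <- tibble::tibble(sample_id = "s1", site = "X1", glycan = c("A", "B"),
                       analyte = c("A", "B"),
                       relative_abundance = c(50, 0))
  f <- parse_trait_formula("A / B", "r")
  out <- suppressWarnings(compute_traits(ra, list(r = f)))
  expect_true(is.na(out$r))
})

test_that("the engine agrees with an independent interpreter on random sets", {
  set.seed(81)
  pool <- c(paste0("IgGI1H", 3:5, "N4"), paste0("IgGI1H", 3:5, "N4F1"),
            "IgGI1H5N4F1S1", "GHOST1", "GHOST2")
  for (rep in 1:40) {
    present <- sample(pool, 6)
    ra <- tibble::tibble(
      sample_id = "s1", site = "IgGI1", glycan = present,
      analyte = present,
      relative_abundance = as.numeric(stats::rmultinom(1, 1000,
                                                       rep(1, 6))) / 10
    )
    abund <- stats::setNames(ra$relative_abundance, ra$analyte)
    texts <- c(random_formula_text(pool), random_formula_text(pool, TRUE))
    formulas <- list(t1 = parse_trait_formula(texts[1], "t1"),
                     t2 = parse_trait_formula(texts[2], "t2"))
    got <- suppressWarnings(compute_traits(ra, formulas))
    for (i in 1:2) {
      want <- interpret_trait_independently(texts[i], abund)
      if (is.na(want)) {
        expect_true(is.na(got[[paste0("t", i)]]))
      } else {
        expect_equal(got[[paste0("t", i)]], want, tolerance = 1e-12)
      }
    }
  }
})

test_that("sum traits are linear and ratio traits scale-invariant", {
  ra <- tibble::tibble(sample_id = "s1", site = "X1",
                       glycan = c("A", "B", "C"),
                       analyte = c("A", "B", "C"),
                       relative_abundance = c(50, 30, 20))
  ra2 <- ra
  ra2$relative_abundance <- ra$relative_abundance * 3
  fs <- list(s = parse_trait_formula("A + 0.5 * B", "s"),
             r = parse_trait_formula("A / A + B", "r"))
  t1 <- suppressWarnings(compute_traits(ra, fs))
  t2 <- suppressWarnings(compute_traits(ra2, fs))
  expect_equal(t2$s, 3 * t1$s)
  expect_equal(t2$r, t1$r)
})

test_that("sum traits with coefficients in [0,1] stay within [0,100]", {
  set.seed(82)
  for (rep in 1:20) {
    vals <- as.numeric(stats::rmultinom(1, 1000, rep(1, 5))) / 10
    ra <- tibble::tibble(sample_id = "s1", site = "X1",
                         glycan = LETTERS[1:5], analyte = LETTERS[1:5],
                         relative_abundance = vals)
    k <- sample(1:5, 1)
    terms <- vapply(sample(LETTERS[1:5], k), function(a) {
      paste(format(round(stats::runif(1), 2), trim = TRUE), "*", a)
    }, "")
    f <- parse_trait_formula(paste(terms, collapse = " + "), "t")
    out <- suppressWarnings(compute_traits(ra, list(t = f)))
    expect_gte(out$t, 0)
    expect_lte(out$t, 100)
  }
})

test_that("the shipped example workbook parses and round-trips", {
  formulas <- parse_trait_formulas(example_trait_formulas())
  expect_gte(length(formulas), 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_formulas(formulas, path)
  again <- parse_trait_formulas(path)
  expect_identical(formulas, again)
})
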