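make_summaries <- function(fractions, intensities = NULL,
                           sample_type = "negative_control", site = "IgGI1",
                           ids = NULL) {
  n <- length(fractions)
  tibble::tibble(
    sample_id = ids %||% sprintf("%s_%02d", sample_type, seq_len(n)),
    site = site,
    sum_intensity = intensities %||% (fractions * 1000),
    passing_fraction = fractions,
    n_targeted = 20L,
    n_passing = as.integer(round(fractions * 20)),
    has_values = TRUE,
    sample_type = sample_type
  )
}

test_that("percentile 100 of the controls is their maximum", {
  s <- make_summaries(c(0.1, 0.2, 0.3, 0.4))
  cut <- cutoffs_from_negative_controls(s, percentile = 100)
  expect_equal(cut$fraction_cutoff, 0.4)
  expect_equal(cut$intensity_cutoff, 400)
})

test_that("a single control defines the cutoff at any percentile", {
  s <- make_summaries(0.25)
  for (p in c(50, 95, 100)) {
    cut <- cutoffs_from_negative_controls(s, percentile = p)
    expect_equal(cut$fraction_cutoff, 0.25)
    expect_equal(cut$intensity_cutoff, 250)
  }
})

test_that("control percentiles match the linear-interpolation definition", {
  set.seed(5)
  vals <- stats::runif(50)
  s <- make_summaries(vals, intensities = stats::rlnorm(50, 10, 1))
  cut <- cutoffs_from_negative_controls(s, percentile = 95)
  expect_equal(cut$fraction_cutoff,
               unname(stats::quantile(vals, 0.95, type = 7)))
  expect_equal(cut$intensity_cutoff,
               unname(stats::quantile(s$sum_intensity, 0.95, type = 7)))
})

test_that("the normal-assumption variant uses mean + z * sd", {
  vals <- c(0.1, 0.2, 0.3, 0.4)
  s <- make_summaries(vals)
  cut <- cutoffs_from_negative_controls(s, percentile = 95, normal = TRUE)
  expect_equal(cut$fraction_cutoff,
               mean(vals) + stats::qnorm(0.95) * stats::sd(vals))
})

test_that("sites without control values degenerate to no exclusion", {
  s <- dplyr::bind_rows(
    make_summaries(c(0.8, 0.9), sample_type = "sample", site = "A1"),
    make_summaries(0.1, site = "B1")
  )
  expect_warning(
    cut <- cutoffs_from_negative_controls(s),
    class = "glycocurate_no_controls"
  )
  a <- cut[cut$site == "A1", ]
  expect_equal(a$intensity_cutoff, -Inf)
  curated <- apply_spectra_curation(s, cut)
  expect_true(all(curated$keep[curated$site == "A1"]))
})

test_that("percentile strategy excludes roughly the stated lowest portion", {
  set.seed(8)
  s <- make_summaries(stats::runif(100, 0.5, 1), sample_type = "sample",
                      intensities = stats::rlnorm(100, 12, 0.5))
  ctl <- make_summaries(0.1)
  cut <- cutoffs_from_percentile(dplyr::bind_rows(s, ctl), percentile = 2)
  curated <- apply_spectra_curation(dplyr::bind_rows(s, ctl), cut)
  excl_samples <- curated[!curated$keep & curated$sample_type == "sample", ]
  # per dimension ~2 lowest at/below cutoff; joint exclusion is >= that
  n_int <- sum(s$sum_intensity <= cut$intensity_cutoff)
  n_frac <- sum(s$passing_fraction <= cut$fraction_cutoff)
  expect_equal(n_int, 2)
  expect_equal(n_frac, 2)
  expect_gte(nrow(excl_samples), max(n_int, n_frac))
  expect_lte(nrow(excl_samples), n_int + n_frac)
})

test_that("percentile 0 excludes nothing", {
  s <- make_summaries(c(0.5, 0.9), sample_type = "sample")
  cut <- cutoffs_from_percentile(s, percentile = 0)
  curated <- apply_spectra_curation(s, cut)
  expect_true(all(curated$keep))
})

test_that("all samples excluded by type is an error", {
  s <- make_summaries(c(0.1, 0.2))
  expect_error(cutoffs_from_percentile(s, percentile = 5),
               class = "glycocurate_cutoffs")
})

test_that("measurements exactly at the cutoffs are excluded under strict rule", {
  s <- make_summaries(c(0.4, 0.5), sample_type = "sample",
                      intensities = c(400, 500))
  cut <- cutoffs_skip("IgGI1")
  cut$intensity_cutoff <- 400
  cut$fraction_cutoff <- 0.4
  cut$strategy <- "negative_control"
  curated <- apply_spectra_curation(s, cut)
  expect_identical(curated$keep, c(FALSE, TRUE))
  inclusive <- apply_spectra_curation(s, cut, rule = "inclusive")
  expect_identical(inclusive$keep, c(TRUE, TRUE))
})

test_that("the skip strategy keeps every measurement", {
  s <- make_summaries(c(0, 0.1, 1), sample_type = "sample")
  s$has_values[1] <- FALSE
  curated <- apply_spectra_curation(s, cutoffs_skip(s$site))
  expect_true(all(curated$keep))
})

test_that("missing-value measurements follow the chosen policy", {
  s <- make_summaries(c(0.9, 0.8), sample_type = "sample")
  s$has_values[2] <- FALSE
  cut <- cutoffs_skip("IgGI1")
  cut$strategy <- "negative_control"
  cut$intensity_cutoff <- 10
  cut$fraction_cutoff <- 0.1
  excl <- apply_spectra_curation(s, cut, missing_policy = "exclude")
  expect_identical(excl$keep, c(TRUE, FALSE))
  expect_identical(excl$reason[2], "no_values")
  zero <- apply_spectra_curation(s, cut, missing_policy = "zero")
  expect_identical(zero$keep, c(TRUE, FALSE))
  expect_identical(zero$reason[2], "low_intensity_and_fraction")
})

test_that("sites are curated independently of each other's data", {
  set.seed(13)
  a <- make_summaries(stats::runif(30, 0.3, 1), sample_type = "sample",
                      site = "A1", ids = sprintf("s%02d", 1:30))
  a_ctl <- make_summaries(c(0.2, 0.35), site = "A1")
  b1 <- make_summaries(stats::runif(30), sample_type = "sample", site = "B1",
                       ids = sprintf("s%02d", 1:30))
  b2 <- make_summaries(stats::runif(30, 0.8, 1), sample_type = "sample",
                       site = "B1", ids = sprintf("s%02d", 1:30))
  b_ctl <- make_summaries(0.5, site = "B1")
  kept_a <- function(other) {
    all_s <- dplyr::bind_rows(a, a_ctl, other, b_ctl)
    cut <- cutoffs_from_negative_controls(all_s, percentile = 100)
    curated <- apply_spectra_curation(all_s, cut)
    sort(curated$sample_id[curated$keep & curated$site == "A1"])
  }
  expect_identical(kept_a(b1), kept_a(b2))
})

test_that("raising the percentile never grows the kept set", {
  set.seed(14)
  s <- dplyr::bind_rows(
    make_summaries(stats::runif(60, 0.2, 1), sample_type = "sample",
                   intensities = stats::rlnorm(60, 11, 0.8)),
    make_summaries(stats::runif(6, 0, 0.4),
                   intensities = stats::rlnorm(6, 8, 0.5))
  )
  kept <- function(p, strategy) {
    cut <- if (strategy == "nc") {
      cutoffs_from_negative_controls(s, percentile = p)
    } else {
      cutoffs_from_percentile(s, percentile = p)
    }
    curated <- apply_spectra_curation(s, cut)
    curated$sample_id[curated$keep]
  }
  for (strategy in c("nc", "pct")) {
    ps <- if (strategy == "nc") c(50, 75, 90, 95, 100) else c(1, 2, 5, 10, 20)
    sets <- lapply(ps, kept, strategy = strategy)
    for (i in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
    }
  }
})

test_that("negative-control curation at percentile 100 excludes every control", {
  set.seed(15)
  s <- dplyr::bind_rows(
    make_summaries(stats::runif(40, 0.5, 1), sample_type = "sample",
                   intensities = stats::rlnorm(40, 12, 0.3)),
    make_summaries(stats::runif(8, 0.05, 0.3),
                   intensities = stats::rlnorm(8, 8, 0.3))
  )
  cut <- cutoffs_from_negative_controls(s, percentile = 100)
  curated <- apply_spectra_curation(s, cut)
  expect_false(any(curated$keep[curated$sample_type == "negative_control"]))
})

test_that("planted dominated spectra are recovered exactly from the simulator", {
  sim <- simulate_dataset(tiny_spec(seed = 44),
                          outdir = withr::local_tempdir())
  rec <- read_lacytools(sim$files$lacytools)
  rec <- link_plate_layout(rec, sim$files$layout)
  types <- infer_sample_types(rec$sample_id)
  rec <- dplyr::left_join(rec, types, by = "sample_id")
  s <- summarize_spectra(rec, quality_criteria("lacytools"))
  cut <- cutoffs_from_negative_controls(s, percentile = 100)
  curated <- apply_spectra_curation(s, cut)
  truth <- sim$spectra
  m <- match(paste(curated$sample_id, curated$site),
             paste(truth$sample_id, truth$site))
  expect_identical(curated$keep, truth$keep_intended[m])
})
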