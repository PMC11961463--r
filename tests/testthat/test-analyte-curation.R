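freq_records <- function(n_pass, n_total, glycan = "H3N4", charge = 2L,
                         group = "A") {
  rec <- make_records(sprintf("%s_s%03d", group, seq_len(n_total)),
                      glycan = glycan, charge = charge)
  rec$pass_overall <- seq_len(n_total) <= n_pass
  rec$biological_group <- group
  rec
}

test_that("passing frequency is n_pass over eligible measurements", {
  rec <- freq_records(40, 80)
  f <- passing_frequency(rec, grouping = "all")
  expect_equal(f$n_pass, 40)
  expect_equal(f$n_eligible, 80)
  expect_equal(f$frequency, 0.5)
})

test_that("per-sample frequencies are 0 or 1", {
  rec <- freq_records(3, 6)
  f <- passing_frequency(rec, grouping = "per_sample")
  expect_true(all(f$frequency %in% c(0, 1)))
  expect_equal(nrow(f), 6)
})

test_that("measurements without values do not count as eligible", {
  rec <- freq_records(2, 4)
  rec$intensity[4] <- NA
  rec$pass_overall[4] <- FALSE
  f <- passing_frequency(rec, grouping = "all")
  expect_equal(f$n_eligible, 3)
  expect_equal(f$frequency, 2 / 3)
})

test_that("frequencies are computed per charge state individually", {
  rec <- dplyr::bind_rows(freq_records(4, 4, charge = 2L),
                          freq_records(1, 4, charge = 3L))
  f <- passing_frequency(rec, grouping = "all")
  expect_equal(f$frequency[f$charge == 2L], 1)
  expect_equal(f$frequency[f$charge == 3L], 0.25)
})

test_that("small biological groups trigger a warning", {
  rec <- dplyr::bind_rows(freq_records(3, 5, group = "A"),
                          freq_records(9, 12, group = "B"))
  expect_warning(
    passing_frequency(rec, grouping = "group",
                      group_col = "biological_group"),
    class = "glycocurate_small_group"
  )
})

test_that("a curation subset restricts which measurements inform frequencies", {
  rec <- freq_records(5, 10)
  f <- passing_frequency(rec, grouping = "all",
                         subset_samples = rec$sample_id[1:5])
  expect_equal(f$n_eligible, 5)
  expect_equal(f$frequency, 1)
})

test_that("planted group frequencies are recovered exactly", {
  sim <- simulate_dataset(tiny_spec(seed = 51),
                          outdir = withr::local_tempdir())
  rec <- read_lacytools(sim$files$lacytools)
  rec <- link_plate_layout(rec, sim$files$layout)
  rec <- dplyr::left_join(rec, infer_sample_types(rec$sample_id),
                          by = "sample_id")
  rec <- merge_metadata(rec, sim$files$metadata)
  rec <- evaluate_quality(rec, quality_criteria("lacytools"))
  s <- summarize_spectra(rec)
  curated <- apply_spectra_curation(
    s, cutoffs_from_negative_controls(s, percentile = 100)
  )
  kept <- filter_kept_records(rec, curated)
  study <- sim$samples$sample_id[sim$samples$sample_type == "sample"]
  f <- passing_frequency(kept, grouping = "group",
                         group_col = "biological_group",
                         subset_samples = study)
  truth <- sim$frequencies
  m <- match(paste(f$scope, f$site, f$glycan, f$charge),
             paste(truth$biological_group, truth$site, truth$glycan,
                   truth$charge))
  expect_equal(f$frequency, truth$frequency_intended[m])
})

test_that("OR and AND consensus equal set union and intersection", {
  set.seed(61)
  universe <- tidyr::expand_grid(site = "A1",
                                 glycan = sprintf("H%dN4", 1:12),
                                 charge = c(2L, 3L))
  for (rep in 1:25) {
    fa <- universe
    fa$scope <- "grpA"
    fa$frequency <- stats::runif(nrow(fa))
    fb <- universe
    fb$scope <- "grpB"
    fb$frequency <- stats::runif(nrow(fb))
    freq <- dplyr::bind_rows(fa, fb)
    freq$n_pass <- round(freq$frequency * 50)
    freq$n_eligible <- 50L
    min_freq <- stats::runif(1, 0.2, 0.8)
    key <- function(d) paste(d$site, d$glycan, d$charge)
    list_a <- key(fa[fa$frequency >= min_freq, ])
    list_b <- key(fb[fb$frequency >= min_freq, ])
    or_truth <- union(list_a, list_b)
    and_truth <- intersect(list_a, list_b)
    if (length(or_truth) == 0) next
    or_got <- build_consensus(freq, min_freq, "OR")
    expect_setequal(key(or_got), or_truth)
    if (length(and_truth) > 0) {
      and_got <- build_consensus(freq, min_freq, "AND")
      expect_setequal(key(and_got), and_truth)
      expect_true(all(key(and_got) %in% key(or_got)))
    }
  }
})

test_that("the paper-style group merge keeps group-specific analytes", {
  freq <- tibble::tibble(
    scope = rep(c("ICU", "non_ICU"), each = 3),
    site = "IgGI1",
    glycan = rep(c("H3N5F1", "H5N4", "H4N4F1"), 2),
    charge = 2L,
    n_pass = c(9, 2, 10, 1, 9, 10),
    n_eligible = 10L
  )
  freq$frequency <- freq$n_pass / freq$n_eligible
  or <- build_consensus(freq, 0.5, "OR")
  expect_setequal(or$glycan, c("H3N5F1", "H5N4", "H4N4F1"))
  and <- build_consensus(freq, 0.5, "AND")
  expect_setequal(and$glycan, "H4N4F1")
})

test_that("min_freq is inclusive and monotone", {
  freq <- tibble::tibble(scope = "all", site = "A1",
                         glycan = sprintf("H%dN1", 1:5), charge = 2L,
                         n_pass = c(10, 8, 5, 3, 0), n_eligible = 10L)
  freq$frequency <- freq$n_pass / freq$n_eligible
  c50 <- build_consensus(freq, 0.5, "OR")
  expect_true("H3N1" %in% c50$glycan)  # exactly at the cutoff
  sizes <- vapply(seq(0, 1, by = 0.1), function(mf) {
    tryCatch(nrow(build_consensus(freq, mf, "OR")), error = function(e) 0L)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("a single group gives identical OR and AND lists", {
  freq <- tibble::tibble(scope = "all", site = "A1",
                         glycan = c("H1N1", "H2N1"), charge = 2L,
                         n_pass = c(8, 2), n_eligible = 10L)
  freq$frequency <- freq$n_pass / freq$n_eligible
  or <- build_consensus(freq, 0.5, "OR")
  and <- build_consensus(freq, 0.5, "AND")
  expect_equal(tibble::as_tibble(or)[c("site", "glycan", "charge")],
               tibble::as_tibble(and)[c("site", "glycan", "charge")],
               ignore_attr = TRUE)
})

test_that("an empty consensus is an error", {
  freq <- tibble::tibble(scope = "all", site = "A1", glycan = "H1N1",
                         charge = 2L, n_pass = 0, n_eligible = 10L,
                         frequency = 0)
  expect_error(build_consensus(freq, 0.5, "OR"),
               class = "glycocurate_consensus")
})

make_demo_consensus <- function() {
  freq <- tibble::tibble(scope = "all", site = "A1",
                         glycan = c("H1N1", "H2N1", "H3N1"), charge = 2L,
                         n_pass = c(9, 8, 1), n_eligible = 10L)
  freq$frequency <- freq$n_pass / freq$n_eligible
  build_consensus(freq, 0.5, "OR")
}

test_that("overrides force entries in and out with provenance flags", {
  cons <- make_demo_consensus()
  ov <- tibble::tibble(site = "A1", glycan = c("H3N1", "H2N1"),
                       charge = 2L, keep = c(TRUE, FALSE))
  out <- apply_overrides(cons, ov)
  expect_setequal(out$glycan, c("H1N1", "H3N1"))
  expect_true(out$override[out$glycan == "H3N1"])
  expect_false(out$override[out$glycan == "H1N1"])
})

test_that("overrides are idempotent and empty overrides are identity", {
  cons <- make_demo_consensus()
  expect_identical(apply_overrides(cons, tibble::tibble()), cons)
  ov <- tibble::tibble(site = "A1", glycan = "H3N1", charge = 2L,
                       keep = TRUE)
  once <- apply_overrides(cons, ov)
  twice <- apply_overrides(once, ov)
  expect_identical(tibble::as_tibble(once), tibble::as_tibble(twice))
})

test_that("overrides referencing unknown entries are an error", {
  cons <- make_demo_consensus()
  ov <- tibble::tibble(site = "A1", glycan = "H9N9", charge = 2L,
                       keep = TRUE)
  expect_error(apply_overrides(cons, ov), class = "glycocurate_override")
})

test_that("consensus curation removes non-retained entries everywhere", {
  cons <- make_demo_consensus()
  rec <- dplyr::bind_rows(
    make_records(c("s1", "s2"), site = "A1", glycan = "H1N1"),
    make_records(c("s1", "s2"), site = "A1", glycan = "H3N1")
  )
  rec$pass_overall <- TRUE
  out <- apply_analyte_curation(rec, cons)
  expect_setequal(unique(out$glycan), c("H1N1", "H2N1")[
    c("H1N1", "H2N1") %in% unique(rec$glycan)])
  expect_false("H3N1" %in% out$glycan)
})

test_that("per-sample curation removes failures only in their own sample", {
  rec <- make_records(c("s1", "s2"), site = "A1", glycan = "H1N1")
  rec$pass_overall <- c(FALSE, TRUE)
  out <- apply_analyte_curation(rec, per_sample = TRUE)
  expect_identical(out$sample_id, "s2")
})

test_that("frequencies ignore sample order and other sites' data", {
  rec <- dplyr::bind_rows(freq_records(6, 10),
                          freq_records(3, 10, glycan = "H9N2"))
  other_site <- make_records(sprintf("t%d", 1:5), site = "Z9",
                             glycan = "H1N1")
  other_site$pass_overall <- FALSE
  f1 <- passing_frequency(rec, grouping = "all")
  set.seed(2)
  f2 <- passing_frequency(
    dplyr::bind_rows(other_site, rec[sample.int(nrow(rec)), ]),
    grouping = "all"
  )
  key <- function(d) paste(d$site, d$glycan, d$charge)
  m <- match(key(f1), key(f2))
  expect_equal(f1$frequency, f2$frequency[m])
})
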