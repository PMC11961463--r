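## Synthetic-data generator: emits matched LaCyTools- and Skyline-dialect
## files, a 96-well plate layout, metadata and the ground truth of every
## planted outcome, so that each curation stage can be tested end to end
## without external datasets.

#' Specification of a simulated glycoproteomics study
#'
#' The defaults describe the reference study design used throughout the
#' package's tests: 200 study samples (two biological groups), 8 positive
#' control pools and 8 negative controls on 96-well plates; two
#' glycosylation sites, each with 10 glycan compositions quantified in 2
#' charge states (20 analyte-charge combinations per site); 10% of the
#' study-sample spectra planted as low quality. Quality-metric draws are
#' class-separated — records of passing class draw all three metrics well
#' inside the default cutoffs of both dialects, failing-class records well
#' outside — so every planted outcome is unambiguous at the default
#' criteria. Sum intensities of good spectra, negative controls and planted
#' low-quality spectra come from disjoint ranges, making the low-quality
#' spectra strictly dominated in both curation dimensions.
#'
#' Each biological group has one group-specific composition (absent-quality
#' in the other group), emulating qualitative differences between groups
#' that OR-merged consensus lists must preserve.
#'
#' @param seed Integer seed fixing all draws.
#' @param n_samples,n_pools,n_blanks,n_negative_controls Sample-type counts.
#' @param sites Character vector of glycosylation-site names.
#' @param compositions Glycan composition labels quantified on every site.
#' @param charges Integer charge states per composition.
#' @param groups Biological group names, assigned to study samples in
#'   round-robin order.
#' @param group_specific Named list: for each group, compositions that pass
#'   quality only in that group's samples.
#' @param fraction_low_quality Fraction of study-sample spectra planted as
#'   low quality (per site).
#' @param blank_cell_fraction Fraction of good-record cells blanked in the
#'   emitted files (missing values).
#' @param weights Relative-abundance weights per composition (recycled over
#'   sites; normalized internally).
#' @param noise_sdlog Log-sd of the truncated lognormal analyte noise.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1,
                            n_samples = 200,
                            n_pools = 8,
                            n_blanks = 0,
                            n_negative_controls = 8,
                            sites = c("IgGI1", "IgGII1"),
                            compositions = c("H3N4", "H3N4F1", "H4N4",
                                             "H4N4F1", "H5N4", "H5N4F1",
                                             "H3N5F1", "H4N5F1",
                                             "H4N4F1S1", "H5N4F1S1"),
                            charges = c(2L, 3L),
                            groups = c("ICU", "non_ICU"),
                            group_specific = list(ICU = "H3N5F1",
                                                  non_ICU = "H5N4"),
                            fraction_low_quality = 0.10,
                            blank_cell_fraction = 0,
                            weights = NULL,
                            noise_sdlog = 0.15) {
  if (length(compositions) == 0 || length(sites) == 0 ||
      length(charges) == 0) {
    abort_glyco("simulation needs at least one site, composition and charge",
                "glycocurate_simspec")
  }
  if (n_samples < 1) {
    abort_glyco("simulation needs at least one study sample",
                "glycocurate_simspec")
  }
  stopifnot(all(unlist(group_specific) %in% compositions),
            all(names(group_specific) %in% groups))
  if (is.null(weights)) {
    # decreasing profile: abundant core glycoforms, rare sialylated tails
    weights <- rev(sort(seq_along(compositions)^1.5))
  }
  weights <- rep_len(weights, length(compositions))
  weights <- weights / sum(weights)
  structure(list(
    seed = as.integer(seed), n_samples = n_samples, n_pools = n_pools,
    n_blanks = n_blanks, n_negative_controls = n_negative_controls,
    sites = sites, compositions = compositions, charges = as.integer(charges),
    groups = groups, group_specific = group_specific,
    fraction_low_quality = fraction_low_quality,
    blank_cell_fraction = blank_cell_fraction,
    weights = stats::setNames(weights, compositions),
    noise_sdlog = noise_sdlog,
    # disjoint sum-intensity ranges (arbitrary units), log-uniform draws
    intensity_ranges = list(good = c(5e5, 5e6), negative_control = c(5e3, 2e4),
                            bad = c(1e2, 1e3)),
    # class-separated metric ranges per dialect convention
    metric_ranges = list(
      pass = list(mass_lacytools = c(-10, 10), ipq = c(0, 0.15),
                  sn = c(20, 200), mass_skyline = c(-1, 1),
                  idotp = c(0.92, 1)),
      fail = list(mass_lacytools = c(30, 60), ipq = c(0.4, 1),
                  sn = c(0.5, 5), mass_skyline = c(3, 6),
                  idotp = c(0.3, 0.8))
    ),
    charge_shares = stats::setNames(
      rev(sort(seq_along(charges)))^2 / sum(rev(sort(seq_along(charges)))^2),
      charges
    )
  ), class = "simulation_spec")
}

# truncated lognormal noise factor, bounded within +-2 log-sd
trunc_lognorm <- function(n, sdlog) {
  exp(stats::qnorm(stats::runif(n, stats::pnorm(-2), stats::pnorm(2))) * sdlog)
}

runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

runif_range <- function(n, range) {
  stats::runif(n, range[1], range[2])
}

#' Simulate a glycoproteomics study with known ground truth
#'
#' Draws a full study according to `spec`, optionally writes the upstream
#' files (both dialects plus layout and metadata) to `outdir`, and returns
#' the in-memory tables together with the planted ground truth. Both dialect
#' files encode the same underlying intensity draws, with quality metrics
#' expressed in each dialect's own convention, so pipeline outcomes on the
#' two files can be compared.
#'
#' @param spec A [simulation_spec()].
#' @param outdir Optional directory; when given, writes `lacytools.txt`,
#'   `skyline.csv`, `plate_layout.csv`, `metadata.csv` and
#'   `ground_truth.json` there.
#' @return A list with `samples` (annotation incl. plate/well/group),
#'   `records` (ground-truth record table with both dialects' metrics and
#'   `pass_intended`), `spectra` (per sample x site: `class` and
#'   `keep_intended`), `frequencies` (intended per-group passing
#'   frequencies), `abundance` (planted relative-abundance weights, %),
#'   `files` (paths, when written) and `spec`.
#' @export
simulate_dataset <- function(spec = simulation_spec(), outdir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)

  ## ---- samples, plates, wells -------------------------------------------
  ids <- c(
    sprintf("patient_%03d", seq_len(spec$n_samples)),
    if (spec$n_pools > 0) sprintf("pool_%02d", seq_len(spec$n_pools)),
    if (spec$n_blanks > 0) sprintf("blank_%02d", seq_len(spec$n_blanks)),
    if (spec$n_negative_controls > 0)
      sprintf("negcon_%02d", seq_len(spec$n_negative_controls))
  )
  types <- c(
    rep("sample", spec$n_samples),
    rep("pool", spec$n_pools),
    rep("blank", spec$n_blanks),
    rep("negative_control", spec$n_negative_controls)
  )
  n_total <- length(ids)
  n_plates <- ceiling(n_total / 96L)
  # controls round-robin over plates, study samples fill remaining capacity
  plate_assign <- integer(n_total)
  is_ctl <- types != "sample"
  plate_assign[is_ctl] <- rep_len(seq_len(n_plates), sum(is_ctl))
  capacity <- 96L - tabulate(plate_assign[is_ctl], n_plates)
  plate_assign[!is_ctl] <- rep(seq_len(n_plates), times = capacity)[
    seq_len(sum(!is_ctl))]
  wells_all <- paste0(rep(WELL_ROWS, each = 12), rep(WELL_COLS, times = 8))
  well <- character(n_total)
  for (p in seq_len(n_plates)) {
    idx <- which(plate_assign == p)
    well[idx] <- wells_all[seq_along(idx)]
  }
  group <- rep(NA_character_, n_total)
  group[types == "sample"] <- rep_len(spec$groups, spec$n_samples)
  samples <- tibble::tibble(
    sample_id = ids,
    sample_type = types,
    biological_group = group,
    plate = paste0("plate", plate_assign),
    well = well,
    measurement_file = paste0("plate", plate_assign, "_", well),
    age = round(stats::runif(n_total, 20, 80))
  )

  ## ---- spectrum classes -------------------------------------------------
  spectra <- tidyr::expand_grid(sample_id = ids, site = spec$sites)
  spectra <- dplyr::left_join(
    spectra, samples[c("sample_id", "sample_type", "biological_group")],
    by = "sample_id"
  )
  spectra$class <- dplyr::case_when(
    spectra$sample_type == "pool" ~ "good",
    spectra$sample_type == "blank" ~ "blank",
    spectra$sample_type == "negative_control" ~ "negative_control",
    TRUE ~ "good"
  )
  study_idx <- which(spectra$sample_type == "sample")
  n_bad <- round(spec$fraction_low_quality * length(study_idx))
  if (n_bad > 0) {
    spectra$class[sample(study_idx, n_bad)] <- "bad"
  }
  spectra$keep_intended <- spectra$class == "good"

  ## ---- per-record pass classes and intensities --------------------------
  grid <- tidyr::expand_grid(
    spectra[c("sample_id", "site", "class", "sample_type",
              "biological_group")],
    glycan = spec$compositions,
    charge = spec$charges
  )
  # deterministic pass rule inside good spectra: a composition specific to
  # another biological group fails in this group's samples
  off_panel <- rep(FALSE, nrow(grid))
  for (g in names(spec$group_specific)) {
    comps <- spec$group_specific[[g]]
    off_panel <- off_panel |
      (grid$sample_type == "sample" & !is.na(grid$biological_group) &
         grid$biological_group != g & grid$glycan %in% comps)
  }
  grid$pass_intended <- grid$class == "good" & !off_panel

  # negative controls: a few analyte-charges pass per spectrum
  nc_spectra <- unique(grid[grid$class == "negative_control",
                            c("sample_id", "site")])
  if (nrow(nc_spectra) > 0) {
    ac <- tidyr::expand_grid(glycan = spec$compositions,
                             charge = spec$charges)
    n_ac <- nrow(ac)
    # a handful of passing analyte-charges, capped well below the passing
    # fraction of good spectra (which lose at most one off-panel composition)
    k_max <- max(2L, min(6L, floor(0.3 * n_ac)))
    for (i in seq_len(nrow(nc_spectra))) {
      k <- sample(2:k_max, 1)
      chosen <- ac[sample.int(n_ac, k), ]
      sel <- grid$sample_id == nc_spectra$sample_id[i] &
        grid$site == nc_spectra$site[i]
      hit <- sel & paste(grid$glycan, grid$charge) %in%
        paste(chosen$glycan, chosen$charge)
      grid$pass_intended[hit] <- TRUE
    }
  }

  # spectrum totals from disjoint class ranges
  totals <- spectra
  cls <- ifelse(totals$class %in% c("bad", "blank"), "bad",
                ifelse(totals$class == "negative_control",
                       "negative_control", "good"))
  totals$total_intensity <- NA_real_
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    totals$total_intensity[idx] <-
      runif_log(length(idx), spec$intensity_ranges[[cl]])
  }
  grid <- dplyr::left_join(
    grid, totals[c("sample_id", "site", "total_intensity")],
    by = c("sample_id", "site")
  )
  grid$intensity <- grid$total_intensity *
    unname(spec$weights[grid$glycan]) *
    unname(spec$charge_shares[as.character(grid$charge)]) *
    trunc_lognorm(nrow(grid), spec$noise_sdlog)

  ## ---- quality metrics in both dialect conventions ----------------------
  n <- nrow(grid)
  pass <- grid$pass_intended
  rng <- spec$metric_ranges
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  grid$mass_error_lacytools <- ifelse(
    pass, runif_range(n, rng$pass$mass_lacytools),
    sgn * runif_range(n, rng$fail$mass_lacytools)
  )
  grid$ipq <- ifelse(pass, runif_range(n, rng$pass$ipq),
                     runif_range(n, rng$fail$ipq))
  grid$sn <- ifelse(pass, runif_range(n, rng$pass$sn),
                    runif_range(n, rng$fail$sn))
  grid$mass_error_skyline <- ifelse(
    pass, runif_range(n, rng$pass$mass_skyline),
    sgn * runif_range(n, rng$fail$mass_skyline)
  )
  grid$idotp <- ifelse(pass, runif_range(n, rng$pass$idotp),
                       runif_range(n, rng$fail$idotp))

  ## ---- deliberately blanked cells ---------------------------------------
  grid$blanked <- FALSE
  if (spec$blank_cell_fraction > 0) {
    n_blank <- round(spec$blank_cell_fraction * n)
    grid$blanked[sample.int(n, n_blank)] <- TRUE
  }

  records <- dplyr::left_join(
    grid, samples[c("sample_id", "measurement_file", "plate", "well")],
    by = "sample_id"
  )
  records$analyte <- paste0(records$site, records$glycan)

  ## ---- intended passing frequencies per biological group ----------------
  kept <- records[records$class == "good" &
                    records$sample_type == "sample", ]
  freq <- dplyr::group_by(kept, .data$biological_group, .data$site,
                          .data$glycan, .data$charge)
  freq <- dplyr::summarise(
    freq,
    n_pass = sum(.data$pass_intended & !.data$blanked),
    n_eligible = dplyr::n(),
    .groups = "drop"
  )
  freq$frequency_intended <- freq$n_pass / freq$n_eligible

  abundance <- tidyr::expand_grid(site = spec$sites,
                                  glycan = spec$compositions)
  abundance$weight_pct <- 100 * unname(spec$weights[abundance$glycan])

  out <- list(
    samples = samples,
    records = records,
    spectra = spectra[c("sample_id", "site", "sample_type",
                        "biological_group", "class", "keep_intended")],
    frequencies = freq,
    abundance = abundance,
    files = NULL,
    spec = spec
  )
  if (!is.null(outdir)) {
    out$files <- write_simulated_files(out, outdir)
  }
  out
}

## ---- file emission -------------------------------------------------------

write_simulated_files <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    lacytools = file.path(outdir, "lacytools.txt"),
    skyline = file.path(outdir, "skyline.csv"),
    layout = file.path(outdir, "plate_layout.csv"),
    metadata = file.path(outdir, "metadata.csv"),
    ground_truth = file.path(outdir, "ground_truth.json")
  )
  write_lacytools_file(sim$records, paths$lacytools)
  write_skyline_file(sim$records, paths$skyline)
  readr::write_csv(
    tibble::tibble(plate_position = sim$samples$measurement_file,
                   sample_id = sim$samples$sample_id),
    paths$layout
  )
  meta <- sim$samples[sim$samples$sample_type == "sample",
                      c("sample_id", "biological_group", "age")]
  readr::write_csv(meta, paths$metadata)
  jsonlite::write_json(
    list(spectra = sim$spectra, frequencies = sim$frequencies,
         abundance = sim$abundance),
    paths$ground_truth, dataframe = "rows", digits = NA
  )
  paths
}

num_cell <- function(x) {
  ifelse(is.na(x), "", format(x, trim = TRUE, digits = 15, scientific = FALSE))
}

write_lacytools_file <- function(records, path) {
  files <- unique(records$measurement_file)
  analytes <- unique(records$analyte)
  lines <- character(0)
  measures <- list(
    c("Analyte Intensity (Background Subtracted)", "intensity"),
    c("Mass Accuracy [ppm]", "mass_error_lacytools"),
    c("Isotopic Pattern Quality", "ipq"),
    c("S/N", "sn")
  )
  for (ch in sort(unique(records$charge))) {
    sub <- records[records$charge == ch, ]
    for (ms in measures) {
      vals <- sub[[ms[2]]]
      vals[sub$blanked] <- NA_real_
      m <- matrix(NA_real_, nrow = length(files), ncol = length(analytes),
                  dimnames = list(files, analytes))
      m[cbind(match(sub$measurement_file, files),
              match(sub$analyte, analytes))] <- vals
      lines <- c(
        lines,
        paste0(ms[1], "\tcharge ", ch, "+"),
        paste0("\t", paste(analytes, collapse = "\t")),
        vapply(seq_along(files), function(i) {
          paste(c(files[i], num_cell(m[i, ])), collapse = "\t")
        }, ""),
        ""
      )
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

write_skyline_file <- function(records, path) {
  files <- unique(records$measurement_file)
  key <- dplyr::distinct(records, .data$site, .data$glycan, .data$charge)
  out <- tibble::tibble(
    `Protein name` = key$site,
    Peptide = key$glycan,
    `Precursor Charge` = key$charge
  )
  rec_key <- paste(records$site, records$glycan, records$charge)
  tbl_key <- paste(key$site, key$glycan, key$charge)
  for (f in files) {
    sub <- records[records$measurement_file == f, ]
    m <- match(tbl_key, paste(sub$site, sub$glycan, sub$charge))
    idotp <- sub$idotp[m]
    mass <- sub$mass_error_skyline[m]
    area <- sub$intensity[m]
    blanked <- sub$blanked[m]
    idotp[blanked] <- NA_real_
    mass[blanked] <- NA_real_
    area[blanked] <- NA_real_
    out[[paste(f, "Isotope Dot Product")]] <- idotp
    out[[paste(f, "Average mass error PPM")]] <- mass
    out[[paste(f, "Total area MS1")]] <- area
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Simulate paired light/heavy signals for SIL quantitation
#'
#' Emits a minimal curated record table with one light and one heavy
#' (stable-isotope-labeled) site per quantifying peptide: heavy intensities
#' are lognormal, and light intensities equal
#' `heavy * true_quantity / spike_amount` times multiplicative lognormal
#' noise of log-sd `sigma`.
#'
#' @param seed Integer seed.
#' @param n_samples Number of samples.
#' @param n_peptides Number of quantifying peptides.
#' @param sigma Log-sd of the peptide-level ratio noise.
#' @param true_quantity Planted protein quantity (per sample, arbitrary
#'   amount units).
#' @param spike_amount Spiked SIL amount in the same units.
#' @return A list with `records` (tibble `sample_id`, `site`, `glycan`,
#'   `charge`, `intensity`), `sil_map` and `true_quantity`.
#' @export
simulate_sil <- function(seed = 1, n_samples = 50, n_peptides = 3,
                         sigma = 0.1, true_quantity = 20,
                         spike_amount = 10) {
  set.seed(seed)
  samples <- sprintf("s%03d", seq_len(n_samples))
  peptides <- sprintf("pep%d", seq_len(n_peptides))
  rows <- list()
  for (p in peptides) {
    heavy <- stats::rlnorm(n_samples, meanlog = 12, sdlog = 0.3)
    light <- heavy * (true_quantity / spike_amount) *
      stats::rlnorm(n_samples, 0, sigma)
    rows[[p]] <- tibble::tibble(
      sample_id = rep(samples, 2),
      site = rep(c(p, paste0(p, "_SIL")), each = n_samples),
      glycan = "H3N4",
      charge = 2L,
      intensity = c(light, heavy)
    )
  }
  list(
    records = dplyr::bind_rows(rows),
    sil_map = tibble::tibble(peptide = peptides,
                             heavy_site = paste0(peptides, "_SIL"),
                             spike_amount = spike_amount),
    true_quantity = true_quantity
  )
}
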