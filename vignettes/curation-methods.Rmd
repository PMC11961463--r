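---
title: "Curation methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycocurate)
```

## The curation problem

Label-free LC-MS glycoproteomics quantifies, for every sample, the signal of
many glycopeptide analytes — combinations of a glycosylation site (a peptide
backbone acting as a barcode for its protein and site) and a glycan
composition, often in several charge states. Upstream quantitation tools
(LaCyTools-style or Skyline-style) report, next to each quantity, three
quality metrics: the mass error in ppm, a measure of agreement between the
observed and theoretical isotopologue pattern, and a signal-abundance
measure. Before statistical analysis two curation decisions must be made:

1. **Spectra curation** — which whole (sample, site) measurements are of
   sufficient quality to report at all;
2. **Analyte curation** — which (site, composition, charge) analytes are
   quantifiable consistently enough across the dataset to keep anywhere.

`glycocurate` implements both decisions as explicit, replayable rules, then
normalizes the retained signal per site (total-area normalization, so every
analyte becomes a percentage of its site's summed signal) and optionally
derives glycosylation traits — weighted sums and ratios of relative
abundances such as galactosylation per antenna — from user-supplied
formulas.

## Per-analyte quality rules

A record passes when all three criteria hold. Directionality depends on the
upstream dialect: the LaCyTools isotopic pattern quality (IPQ) measures
deviation from the theoretical pattern (0 is perfect; the rule is
`IPQ <= threshold`), while the Skyline isotope dot product measures
similarity (1 is perfect; `idotp >= threshold`). Defaults follow the
empirically established values for each dialect:

| parameter | LaCyTools default | Skyline default |
|---|---|---|
| mass error window (ppm) | [-20, +20] | [-2, +2] |
| pattern threshold | IPQ ≤ 0.2 | idotp ≥ 0.9 |
| signal threshold | S/N ≥ 9 | area > 0 |

All comparisons are inclusive except the Skyline area bound, which is
strict so that the meaningful default of 0 still rejects zero-area
analytes. A missing value in any criterion — or a missing quantity — fails
the record: a number without its quality metrics is not trustworthy.

## Spectra curation

Each (sample, site) measurement is summarised by two dimensions: the sum
intensity of all quality-passing analytes and the fraction of the site's
*targeted* analyte list that passes. The denominator is always the full
extraction list for the site, so undetected analytes count against the
measurement. We count analyte × charge combinations rather than
compositions, because charge states are curated individually downstream;
counting combinations keeps the two curation steps consistent (this is
configurable in effect by supplying a custom targeted list).

Three strategies derive the per-site 2-D cutoff pair:

* **skip** — no exclusion; appropriate for small datasets where every
  sample is unmissable.
* **negative controls** (recommended) — per dimension, the cutoff is a
  percentile (default 95, linear-interpolation definition, i.e.
  `stats::quantile(type = 7)`) of the values observed in negative-control
  measurements; percentile 100 takes their maximum. An advanced variant
  assumes normality and uses `mean + z(percentile) · sd`. With a single
  control the empirical percentile equals that control's value at any
  percentile. Sites without control values degenerate, with a warning, to
  no exclusion.
* **fixed percentile** — per dimension, the cutoff is a low percentile
  (e.g. the 2nd) of the study samples' own values; control and blank
  sample types must be excluded from this computation. Because the
  percentile applies per dimension, the overall excluded fraction is
  slightly above the nominal percentile. Percentile 0 disables exclusion.

A measurement is kept iff it lies strictly above the cutoff in **both**
dimensions. Strictness is a deliberate choice: with a maximum-based
control cutoff, the controls defining it are then themselves excluded,
which is the behaviour one wants from a negative control. The inclusive
rule (`>=`) is available for datasets curated with other conventions.
Measurements without any values for a site are excluded by default; the
alternative policy scores them as zeros, which under the strict rule
excludes them whenever cutoffs are non-negative. Sites are curated
independently throughout — data quality genuinely differs between sites,
and the tests assert that permuting one site's data never changes
another's kept set.

The percentile definition matters because control sets are small;
linear interpolation between order statistics is the convention used here
and documented so that cutoffs can be reproduced outside the package.

## Analyte curation and consensus lists

Within the measurements that survived spectra curation, each
(site, composition, charge) entry gets a passing frequency: the share of
eligible measurements (those with values for the site) in which it passes
all quality criteria. Frequencies can be computed per sample (yielding 0/1
decisions for qualitative work), over the whole dataset, or per biological
group. Groups should contain at least ten samples; smaller groups trigger
a warning rather than an error, since exploratory runs are legitimate.

Entries reaching the minimum frequency (inclusive, so 50% keeps an
analyte passing in exactly half the measurements; typical values are 80%
for high-quality and 50% for medium-quality data) form each group's list.
Group lists merge by OR (union — preserves group-specific analytes, e.g. a
composition quantifiable only in a diseased group) or AND (intersection).
A frequency subset (e.g. antigen-specific measurements only) may inform
the frequencies while the resulting consensus list is applied to all
measurements; applying the merged consensus to every measurement is the
default, which keeps normalization denominators comparable across
measurement types. Manual overrides — a table of entries with a keep flag
— win over the automated result and are flagged in the consensus
provenance; the operation is idempotent.

Charge states of one composition are retained or dropped independently;
retained charge states are summed per analyte before total-area
normalization. Per (sample, site) the relative abundances then sum to
100% by construction whenever any signal was retained; a zero total
yields missing values rather than a division by zero.

## Trait formula mini-language

Traits are defined by predefined formulas with fixed compositions, not by
structural categorization. The grammar is space-tokenized:

```
formula := sum [ "/" sum ]
sum     := term { "+" term }
term    := [ number "*" ] analyte-name
```

`/` binds last and may occur once; there are no parentheses, and a second
`/` is a parse error rather than a silently chained division. Analyte
names are full names (site prefix plus composition). Formula analytes
absent from the dataset are dropped from both numerator and denominator —
numerically identical to zeroing for sum traits, but for ratio traits
dropping matches the "absent compositions are ignored" semantics; a
`missing_analytes = "zero"` mode keeps denominator terms for users who
prefer the other arithmetic. Dataset analytes covered by no formula
produce a warning listing them, and the formula set can be exported,
extended and re-supplied. Because relative abundances are percentages,
sum traits are percentages directly and ratio traits are reported as
`100 · numerator / denominator`. A zero denominator yields a missing
value. The shipped IgG Fc N-glycan workbook is an illustrative
configuration of the syntax, not a canonical trait catalogue.

## Analyte-name parsing

Analyte names concatenate a site identifier and a composition
(`IgGI1H4N4F1`). The documented "site ends before the first number" rule
breaks on site identifiers that contain digits, so the default split is
*before the first monosaccharide-letter-followed-by-digit token*, which
parses both `IgGI1H4N4F1` (site `IgGI1`) and `peptide1H5N4F1S1`
(site `peptide1`) sensibly. A strict first-digit mode is available; it
ends the site before the first digit and skips digits between site and
composition. The monosaccharide alphabet is configurable and defaults to
H, N, F, S, G. Duplicate compositions on one site are treated as isomers
in Skyline data and renamed with running lowercase letters in order of
appearance (valid when retention order is conserved across samples);
in LaCyTools data duplicates indicate an upstream targeting error and are
rejected.

## Optional features

**SIL quantitation.** With stable-isotope-labeled standards, each
quantifying peptide yields `light/heavy × spiked amount`; the protein
quantity per sample is the median over peptides, making the estimate
robust to a single aberrant peptide, and pairwise Pearson correlations of
per-peptide quantities across samples serve as a quality check. Zero or
missing heavy signal skips the peptide for that sample with a warning.

**Repeatability.** Technical variability comes from repeated measurements
of a control pool. Per (plate, analyte) we report the mean relative
abundance and CV (`100 · sd / mean`, sample sd with n−1); the median
intra-plate CV is taken over all (plate, analyte) cells with at least two
replicates, and the median inter-plate CV is, per analyte, the CV of
plate means, median over analytes. This two-level aggregation is one of
several defensible schemes, so both intermediate tables are returned for
re-aggregation.

## The synthetic-data generator

Every stage is testable without external data through a simulator that
emits matched LaCyTools- and Skyline-dialect files, a 96-well plate
layout, metadata and the full ground truth. Its defaults define the
reference study: 200 study samples in two biological groups, 8 positive
control pools and 8 negative controls distributed over three 96-well
plates; two glycosylation sites with 10 glycan compositions in 2 charge
states each (20 analyte-charge combinations per site); 10% of study
spectra planted as low quality.

Design choices that make planted outcomes unambiguous:

* Quality metrics are class-separated — passing records draw all metrics
  from ranges well inside both dialects' default cutoffs, failing records
  well outside — so the intended pass flag survives any reasonable
  threshold jitter and both dialects agree record by record.
* Spectrum sum intensities come from disjoint log-uniform ranges
  (good 5·10⁵–5·10⁶, negative controls 5·10³–2·10⁴, planted-bad
  10²–10³ arbitrary units), and planted-bad spectra pass no analyte at
  all, so they are strictly dominated by every control in both curation
  dimensions.
* Negative controls pass a small number of analyte-charges (2 up to 30%
  of the panel), placing their passing fractions strictly between the
  planted-bad and good classes.
* Analyte intensities are lognormal around a fixed decreasing
  relative-abundance profile (truncated at ±2 log-sd, log-sd 0.15), and
  each group has one group-specific composition failing in the other
  group — the structure OR-merged consensus lists must preserve.

What the simulator deliberately does **not** emulate: borderline quality
values near the cutoffs, drifting retention times or calibration
failures, correlated noise between analytes, plate effects on study
samples, and missingness mechanisms beyond uniformly random blanked
cells. Passing tests therefore demonstrate the correctness of the rules,
not that the default thresholds are optimal for any particular real
dataset.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (`type = 7`); normal variant uses the
  one-sided standard-normal quantile; a single control yields `sd = 0`.
* Zero-total (sample, site) pairs normalize to missing values.
* Trait denominators of exactly 0 yield missing trait values.
* CVs are undefined (missing) for fewer than two replicates or a zero
  mean; plates with one replicate drop out of the intra-plate median.
* Empty consensus lists are an error: downstream normalization would be
  undefined.
* The wide export keeps one row per sample, with excluded (sample, site)
  measurements as missing values, never dropped rows.

## Reproducibility

The JSON run report records the package version, input-file MD5 digests,
every setting, per-site cutoffs with provenance, exclusion counts per
sample type, the consensus list with per-group frequencies and override
flags, and the trait formulas. Re-running `run_pipeline()` on the
report's recorded settings reproduces kept sets and exports exactly; the
timestamp is the only differing field between identical runs. Exports
are CSV and JSON throughout — plain-text formats that diff and version
well; workbook inputs (plate layout, metadata, trait formulas) are
accepted as XLSX or CSV.

The test suite exercises the reference design (200 samples, 2 sites, 40
analyte-charges) for the end-to-end checks and a reduced design (30
samples, 1 site, 5 compositions) for the per-module tests; randomized
oracle comparisons use 10,000 records for the quality rules, 50
group-list pairs for the consensus algebra and 100 random formula sets
for the trait engine.

## Known limitations

* No raw-spectra handling, peak integration, retention-time alignment or
  m/z calibration — those belong upstream.
* No glycan structure identification and no logic-based trait
  categorization.
* Plate layouts are fixed at 96-well geometry.
* The LaCyTools block dialect is co-defined with the simulator and
  documented in `read_lacytools()`; real-world files with other block
  arrangements need to be exported to the supported form.
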