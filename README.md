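# glycocurate

Automated curation of label-free LC–MS glycoproteomics and glycomics
datasets: a headless R engine (plus a small command-line tool) for everyone
who quantifies glycopeptides or released glycans at cohort scale and needs
to turn raw quantitation-tool output into a statistics-ready table with a
fully replayable audit trail.

## The problem and the method

Upstream quantitation software reports, per sample and per analyte — a
(glycosylation site, glycan composition, charge) triple — a quantity and
three quality metrics: mass error (ppm), an isotopologue-pattern score and
a signal measure. Two dialects are supported: LaCyTools-style summaries
(background-subtracted intensity, mass accuracy, isotopic pattern quality
IPQ where 0 is perfect, signal-to-noise) and Skyline-style reports
(isotope dot product where 1 is perfect, average mass error, total MS1
area). `glycocurate` then makes the two curation decisions explicit:

1. **Spectra curation.** Each (sample, site) measurement *m* is reduced to
   two dimensions: the sum intensity of quality-passing analytes,
   `I(m) = Σ_a∈pass intensity(a)`, and the passing fraction
   `f(m) = n_pass / n_targeted` over the site's full targeted list. A
   measurement is kept iff `I(m) > I_cut` **and** `f(m) > f_cut`, with the
   per-site cutoff pair derived from negative controls (a percentile of
   their values, default the 95th; or `mean + z·sd` under a normality
   assumption), from a fixed lowest percentile of the study samples, or
   skipped entirely.
2. **Analyte curation.** For each analyte-charge entry the passing
   frequency `ν = n_pass / n_eligible` is computed over the surviving
   measurements — per sample, over the whole dataset, or per biological
   group — and entries with `ν ≥ ν_min` (typically 0.5 or 0.8) form each
   group's list; group lists merge into a consensus by union (OR) or
   intersection (AND), with manual overrides tracked in the provenance.

Retained signal is total-area normalized per site (each analyte as % of
the site's summed signal), and glycosylation traits are evaluated from a
small formula language (`trait = Σ cᵢ·xᵢ [ / Σ dⱼ·xⱼ ]`, space-tokenized,
one optional division). Optional features: absolute quantitation from
stable-isotope-labeled (SIL) spikes (median over peptides of
`light/heavy × spike`) and plate-level repeatability (median intra- and
inter-plate CV of technical replicates). A synthetic-data generator with
complete ground truth makes every stage testable offline; see the methods
vignette (`vignettes/curation-methods.Rmd`) for the models, parameter
defaults and design choices.

## Worked example

Simulate the reference study (200 patients in two clinical groups, 8 pool
and 8 negative-control wells on three 96-well plates, two IgG
glycosylation sites) and run the full pipeline with negative-control
spectra curation at the 95th percentile and an OR-merged per-group
consensus at 50%:

```r
library(glycocurate)

sim <- simulate_dataset(simulation_spec(seed = 1), outdir = "demo")
state <- run_pipeline(list(
  input = list(dialect = "lacytools", data = "demo/lacytools.txt",
               layout = "demo/plate_layout.csv",
               metadata = "demo/metadata.csv"),
  spectra_curation = list(strategy = "negative_control", percentile = 95),
  analyte_curation = list(mode = "consensus", grouping = "group",
                          group_col = "biological_group",
                          min_freq = 0.5, logic = "OR")
))

state$cutoffs[, c("site", "intensity_cutoff", "fraction_cutoff", "n_used")]
#>   site   intensity_cutoff fraction_cutoff n_used
#> 1 IgGI1             5753.           0.282      8
#> 2 IgGII1            3475.           0.282      8
sum(state$spectra_curated$keep)
#> [1] 376
```

Of the 432 (sample, site) measurements, 56 fall below the cutoffs: all 16
negative-control measurements plus the 40 planted low-quality spectra
(per-sample-type reasons are in `spectra_exclusion_log()`). All 40
analyte-charge entries reach the 50% frequency in at least one group, so
the OR consensus keeps them, and the wide export carries one row per
sample — metadata, then traits, then site-prefixed relative abundances:

```r
state$wide[1:3, 1:8]
#>   sample_id   plate  well sample_type biological_group age IgGI1H3N4 IgGI1H3N4F1
#> 1 patient_001 plate1 A1   sample      ICU               36      21.4        16.7
#> 2 patient_002 plate1 A2   sample      non_ICU           42      20.5        17.1
#> 3 patient_003 plate1 A3   sample      ICU               54      18.0        17.3
```

Relative abundances per (sample, site) sum to 100 by construction. A JSON
report (`write_report()`) records versions, input digests, every setting,
cutoffs and the consensus provenance; `run_pipeline()` on the report's
recorded settings reproduces the run exactly.

The same steps are available from a shell via the thin wrapper in
`exec/glycocurate` (`run`, `simulate`, `ingest`, `curate-spectra`,
`curate-analytes`, `traits`, `quantify`, `repeatability`), each step
exporting its state as CSV so any stage can be inspected or skipped.

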