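# plasticmine

Mining metagenomes for plastic-degrading enzyme homologues.

Microbial communities in oceans and soils have been exposed to plastic
waste for decades, and enzymes that modify or degrade common polymers
(PET, PU, PHB, PLA, PEG, PBAT, ...) and phthalate-based plasticizer
additives keep turning up in isolates. `plasticmine` is an R package plus
analysis workflow for surveying that potential at scale: it builds an
identity-stratified library of profile scoring models from a curated
enzyme catalog, scores metagenomic gene catalogs against it, controls
false positives with a negative-control (gut-like) catalog, and relates
the resulting hit abundance to habitat structure and geolocated pollution
measurements. It is aimed at environmental microbiologists and
bioinformaticians who want a tested, fully reproducible desk-scale version
of this mining-and-calibration procedure.

## Method at a glance

- **Library.** Curated records are clustered greedily at 95% identity
  (global-alignment identity, shorter-sequence denominator) to pick
  representatives; each representative is expanded with database homologs
  (E < 1e-10) across identity bins 60–90% (step 5%), and a
  position-specific log2-odds matrix with plus-one pseudocounts,
  `log2[(count_c(a)+1)/(n+20) / q(a)]`, is built per (representative, bin).
- **Search.** Each gene's bit score against a model is its best ungapped
  window; empirical E-values are calibrated on seeded residue-shuffle
  decoys, `E(s) = N (1 + #{decoy ≥ s}) / (1 + D)`, with an exponential
  bit-score tail `E(s_max) 2^-(s-s_max)` beyond the top decoy. One best
  hit is kept per gene.
- **Calibration.** Per model, environmental hits are positives and
  control-catalog hits negatives; a model is retained only with ≥ 20
  labelled points, precision-recall AUC ≥ 0.75 and a score threshold
  reaching 99.99% precision. Final hits additionally require E < 1e-16.
- **Ecology & pollution.** Per-sample summaries feed one-vs-rest rank-sum
  habitat scans, Spearman covariate scans, Bray-Curtis PCoA, and — after
  pooling heterogeneous pollution surveys by per-survey Box-Cox transform
  and z-scoring — haversine nearest-point matching within 400 km, Spearman
  correlation and a Siegel repeated-median trend fit
  (`slope = median_i median_j (y_j-y_i)/(x_j-x_i)`).

A synthetic-data generator emulates every input (enzyme families with
controlled divergence, catalogs with planted homologues, composition-
matched control decoys, geolocated samples, multi-scale pollution surveys
coupled to a latent field at a chosen Spearman strength), so the whole
pipeline runs and is tested without any external downloads. See the
methods vignette (`vignettes/mining-plastic-degradomes.Rmd`) for the
model, parameter and design details.

## Worked example

The numbered drivers under `analysis/` run the full synthetic study and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_build_library.R
Rscript analysis/03_search.R
Rscript analysis/04_calibrate.R
Rscript analysis/05_aggregate.R
Rscript analysis/06_ecology_stats.R
Rscript analysis/07_pollution_link.R
```

At the default configuration (seed 1) this prints, among other output:

```
Clustered 80 records into 80 representatives at 95% identity.
Built 560 models across identity bins 0.60-0.90.
...
After best-hit-per-gene reduction: 1563 environmental, 397 control.
Retained 20 of 560 models (3.6%).
Final hits: 1217. Precision vs truth 1.000, planted recall 0.989,
families with a retained model: 100%.
...
At 400 km: 40/40 samples matched; Spearman rho = 0.330 (p = 0.038);
repeated-median trend: 1.68 hits per pollution z-unit (intercept 30.1).
```

Reading: of 4,000 environmental genes, 1,217 survive the calibrated
filter; every one of them is a planted homologue (precision 1.000) and
98.9% of planted homologues are recovered by a model of their source
family, while only 3.6% of the 560 models pass the retention gates —
the negative-control calibration is doing the same aggressive
false-positive pruning it performs in the published study. The
per-sample hit counts then correlate positively with the pooled pollution
field they were generated to track.

The same workflow reproduces the published overview-table arithmetic from
the packaged per-dataset counts (stage 05): 30,025 total hits, additive
shares of 69% (soil) vs 39% (ocean), 7,506 mean per-dataset hits, ocean
hits-per-gene 1.11e-04, and a 10% retained-model fraction.

## Layout

- `R/` — package code: generator, library construction, search,
  calibration, aggregation, ecological statistics, pollution linkage.
- `analysis/` — numbered drivers for the end-to-end synthetic study.
- `tests/testthat/` — unit, property and acceptance tests (brute-force
  oracles for every nontrivial reduction).
- `inst/extdata/` — the published per-dataset count fixture.
- `vignettes/` — the methods vignette.
- `scripts/acceptance.R` — see above.
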