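---
title: "Mining metagenomes for plastic-degrading enzyme homologues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining metagenomes for plastic-degrading enzyme homologues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Environmental microbiomes are exposed to decades of accumulating plastic
waste, and scattered experimental work has isolated enzymes that modify or
degrade specific polymers (PET, PU, PHB, PLA, PEG, PBAT, ...) and
phthalate-based plasticizer additives. `plasticmine` implements a pipeline
for asking, at survey scale, *how much plastic-degrading potential a set of
metagenomic gene catalogs carries and whether that potential tracks
measured pollution*. The pipeline has five stages:

1. **Library construction** (`build_library_from_catalog`): a curated
   catalog of verified enzymes is clustered greedily at 95% identity to
   pick representatives; each representative is expanded with database
   homologs (E-value < 1e-10) stratified across identity cutoffs from 60%
   to 90% in 5% steps, and one position-specific scoring model is built per
   (representative, identity bin).
2. **Search** (`score_catalog`, `deduplicate_hits`): every gene in every
   catalog is scored against every model; E-values are calibrated against
   residue-shuffle decoys; only the best-scoring model is kept per gene.
3. **Negative-control calibration** (`calibrate_library`, `filter_hits`):
   hits from a habitat assumed free of the target function (a gut-like
   control catalog) are treated as labelled false positives. Per model, a
   precision-recall curve of environmental-vs-control bit scores gates
   retention (at least 20 points, PR-AUC at least 0.75) and sets a score
   threshold at 99.99% precision. Final hits must additionally pass
   E < 1e-16.
4. **Aggregation** (`summarize_samples`, `summarize_datasets`, ...):
   per-sample and per-dataset hit counts, degradable-plastic-type counts,
   the polymer/additive partition, EC-annotation coverage and
   per-genome-bin profiles.
5. **Ecology and pollution linkage** (`habitat_scan`, `pcoa_ordination`,
   `pool_surveys`, `match_pollution`, `correlate_pollution`): rank-based
   habitat scans and covariate correlations, Bray-Curtis ordination, and
   correlation of per-sample hit counts with pooled geolocated pollution
   measurements, with a Siegel repeated-median trend fit.

Because the underlying metagenome, gut and expedition datasets are large
external resources, the package ships a synthetic-data generator
(`generator_config` and the `generate_*` functions) that emulates every
input with controllable ground truth. All tests and the acceptance script
run on synthetic data; section *What the generator does and does not show*
discusses what that implies.

## The scoring model

The built-in scorer is a deliberately simple surrogate for profile-HMM
search, chosen to be deterministic, fast and fully checkable by hand:

* A model over an $L$-column representative holds per-column residue
  probabilities with plus-one pseudocounts, $p_{c}(a) = (n_{c}(a) + 1) /
  (n + 20)$, where $n_c(a)$ counts members (globally aligned to the
  representative) carrying residue $a$ at representative column $c$ and
  $n$ is the member count. The score matrix is the log-odds
  $\log_2 p_c(a) / q(a)$ against a background $q$ (uniform by default),
  so scores are in bits.
* A gene's bit score is its best ungapped full-overlap window against the
  matrix. Gapped and domain-level alignment are out of scope — at the
  divergences the generator produces (and at which the identity bins
  operate), ungapped window scores separate homologues from background by
  hundreds of bits.
* E-values are empirical: with $N$ catalog genes and $D$ decoy scores
  (seeded residue shuffles of catalog genes, 10,000 by default),
  $E(s) = N \, (1 + \#\{d \ge s\}) / (1 + D)$. Beyond the largest decoy
  score $s_{max}$ the estimator saturates at its floor $N/(1+D)$, which
  can never reach the strict reporting cutoffs the calibration stage uses
  (E < 1e-16). The tail is therefore extended as
  $E(s) = \frac{N}{1+D} \, 2^{-(s - s_{max})}$: scores are log2 odds, so
  each additional bit halves the expected number of chance matches — the
  standard extreme-value form for bit scores. The resulting E-value is
  non-increasing in the score, matches the empirical estimator everywhere
  the decoys can see, and lets well-separated homologues reach arbitrarily
  small E-values, as real search tools do.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| representative clustering cutoff | 0.95 | identity fraction | collapse near-duplicates in the curated catalog |
| expansion E-value cutoff | 1e-10 | E | inclusion of database homologs |
| identity grid | 0.60–0.90, step 0.05 | fraction | stratified model specificity |
| `precision_target` | 0.9999 | precision | per-model score threshold |
| `auc_min` | 0.75 | PR-AUC | model retention gate |
| `min_points` | 20 | labelled hits | minimum evidence per model |
| `evalue_max` | 1e-16 | E | final hit gate |
| matching radius | 400 | km | pollution nearest-point cutoff (sensitivity analysis over 100–1600 km provided) |
| decoys per catalog | 10,000 | scores | E-value resolution |

The filter defaults are the study conditions this pipeline reproduces and
should not be changed casually: loosening `precision_target` or `auc_min`
trades false-positive control for recall in exactly the way the
precision-recall machinery quantifies.

Identity is defined as matching columns of a global alignment (match +1,
mismatch 0, linear gap −1) divided by the shorter sequence's length —
the semantics of the usual greedy clustering tools, which never being
stated exactly anywhere, we fix and document. The greedy order is length
descending with lexicographic id tie-break, making the clustering
deterministic and oracle-checkable; accelerator heuristics (word size,
cluster size) of the original tools are deliberately not reproduced.

Bin assignment is **cumulative** by default: a database sequence at 0.8
identity to its representative enters every bin from 0.60 to 0.80. The
alternative, assigning each sequence only to its own identity bracket, is
available (`mode = "bracket"`); published per-cutoff model counts are
consistent with either reading, and cumulative gives the monotone
bin-nesting property that the tests assert.

Hit deduplication is global per gene (the best model wins, ties broken by
bit score then lexicographic model id); a per-(gene, model) mode is
available behind `per_model = TRUE`. The same reduction is applied to the
control catalog before calibration. The `min_points` gate counts combined
environmental + control hits by default (`points = "env_only"` is the
alternative reading).

PR-AUC is a trapezoid over recall anchored at (recall 0, precision of the
highest-score point); a step-wise average-precision alternative is
provided (`method = "step"`). The retention decision names every failed
gate, and the score threshold is the *smallest* distinct score reaching
the precision target, keeping maximal recall at that precision.

## The synthetic-data generator

`generator_config()` defaults define the study conditions used throughout:

* 20 enzyme families, 4 members each (~80 reference enzymes, the order of
  the real curated catalog), 200-residue sequences, within-family
  divergence 0.2 substitutions/site (substitutions drawn uniformly from
  the 19 alternative residues, so expected identity to the ancestor is
  0.8, and member-member identity ~0.66 — squarely inside the 0.60–0.90
  bin grid);
* 40 samples of 100 genes; on average 30% of each sample's genes are
  planted homologues (drawn from family ancestors at the same divergence),
  the rest i.i.d. uniform background;
* a 2,000-gene control catalog: half background, half *near-decoys* —
  residue shuffles of family members. These are composition-matched
  negatives, stressing the calibration filter the way shared-ancestry gut
  homologues do in real data;
* geolocated samples with three depth-layer regimes (surface ~5 m, deep
  chlorophyll maximum ~71 m, mesopelagic ~600 m), region labels, a
  temperature covariate, and a standard-normal latent pollution field;
* 4 pollution surveys on scales spanning three orders of magnitude
  (×1, ×10, ×100, ×1000), each measuring a lognormal transform of the
  field with 0.1-sd log-scale noise at coordinates jittered ±0.5° around
  the samples it covers (samples assigned round-robin, so the surveys
  jointly cover every sample within ~80 km).

Planted counts are coupled to the field through a Gaussian copula: a
latent normal correlated with the field at Pearson
$2\sin(\pi\rho_s/6)$ — the bivariate-normal inverse of Spearman's
$\rho_s$ — is pushed through the binomial quantile function. This yields
integer counts with the configured mean whose *population* Spearman
correlation with the field equals `target_rho` up to the (small)
tie-induced attenuation of the discrete marginal; the test suite verifies
convergence at $n = 500$ within ±0.05. At $n = 60$ a single draw's
empirical Spearman has sampling standard deviation near 0.1, so recovery
checks average over a block of five consecutive seeds rather than relying
on one draw.

**What passing tests do and do not show.** The generator produces i.i.d.
background, substitution-only divergence (no indels, no domain shuffling),
uniform residue background and length-homogeneous genes. Passing the
calibration criteria on this data shows the machinery is correct and the
gates behave as designed; it does not show that the surrogate scorer
matches profile-HMM sensitivity on real protein families, nor that real
gut catalogs behave like shuffled decoys. For real data the scorer stage
is pluggable: per-target tabular output of an external search tool can be
ingested with `read_search_table()` and flows through the identical
calibration, aggregation and correlation stages.

## Numerical choices

* Box-Cox lambda is fitted by maximizing the profile log-likelihood with
  bounded search on [−5, 5] to tolerance 1e-6; non-positive survey values
  are shifted by $1 - \min(x)$ first, and the shift and lambda are
  recorded in the pooled table's attributes. Surveys are z-scored
  *per survey* after transformation (a `global_z` flag pools first); the
  per-survey form makes pooled values invariant in rank, and nearly in
  value, to positive rescalings of any one survey.
* Great-circle distances use the haversine form on the IUGG mean sphere
  (6371.0088 km). Nearest-point ties are broken by (survey id, point
  index).
* The repeated-median fit excludes equal-x pairs from inner medians and
  uses `stats::median` (mean-of-two) at even counts; it is order-invariant
  and has 50% breakdown.
* Rank-sum p-values: exact Wilcoxon distribution for untied data, full
  enumeration of group assignments for tied data up to combined n = 12
  (so identical groups give exactly p = 1), and a tie-corrected normal
  approximation without continuity correction otherwise — at these sizes
  the uncorrected form tracks the exact two-sided p within a few percent,
  while the continuity-corrected form can deviate by more than 10%.
* Spearman's rho is the Pearson correlation of mid-ranks with a
  t-approximation p-value (n − 2 df); zero rank variance is flagged
  rather than propagated as NaN.
* PCoA drops negative eigenvalues from the variance-explained denominator
  (no Lingoes/Cailliez correction) and screens eigenvalues at a relative
  1e-8 tolerance. The ordination feature space is counts per retained
  model per sample — finer than plastic type; aggregate first if a
  per-type ordination is wanted.
* All generated tables carry a `#seed=` provenance header; every random
  stage derives a dedicated sub-seed from the configuration seed, so each
  `generate_*` call is independently reproducible and fixed seeds give
  byte-identical FASTA/TSV outputs.

## Problem sizes

The packaged analyses and tests run the full synthetic study at its
default size — 80 reference enzymes, 560 models, 4,000 environmental and
2,000 control genes, 10,000 decoy scores per catalog — which completes in
about a minute and a half on one CPU; unit tests use a reduced
configuration (4 families, 120-residue sequences, 12 samples) for
sub-second feedback. Recovery analyses use n = 60 samples for the
pollution coupling and n = 500 for distributional checks.

## Known limitations

* The surrogate scorer is ungapped and single-segment; genes much longer
  than a model are scanned by windows, but fragmented or multi-domain
  homology will be underscored relative to a true profile HMM.
* Empirical E-values below the decoy floor rely on the exponential tail
  extension; between the floor and ~1e-16 the calibration is asymptotic,
  not resampled.
* The generator's background model is uniform i.i.d.; compositionally
  biased real catalogs will shift decoy score distributions, which is
  exactly what the per-model calibration absorbs, but absolute E-values
  are not comparable across catalogs with very different compositions.
* Country-level waste linkage is an exact key join; no spatial
  disaggregation below country level is attempted.
* Coordinates live on a sphere; no geodetic datum handling.
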