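---
title: "Benchmarking species-level 16S profiles against mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking species-level 16S profiles against mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockbench)
```

## The problem

Short-read 16S rRNA amplicon protocols that sequence multiple variable
regions promise species-level taxonomic resolution, but that promise has to
be demonstrated, not assumed. The standard instrument for doing so is a
defined mock community — a mixture of known species with supplier-stated
("theoretical") abundances — carried through the workflow in two roles:
whole cells entering at DNA extraction (an *extraction control*, sensitive
to lysis bias) and purified DNA entering at library preparation (a
*sequencing control*, sensitive to amplification and sequencing bias).
Together with technical replicate pairs run within and across sequencing
plates, mock controls let a lab answer three questions: is the classifier
right at species rank, is the measured composition biased, and are the
results reproducible?

`mockbench` implements that evaluation as a reusable, tested pipeline for
taxa-by-sample abundance tables. It does not process reads: its input is the
species-level profile some upstream pipeline produced.

## Data model

The central container, `AbundanceTable`, extends `SummarizedExperiment`: a
non-negative taxa × samples matrix with the parsed lineage in `rowData`.
Taxon identity is the full canonical lineage string
(`k__...;p__...;...;g__...;s__...`), so a genus-only record
(`g__Bacillus;s__`) and a species record of the same genus are distinct
rows — mock evaluation depends on that distinction. Three value modes are
supported: `counts`, `relative` (columns closed to 1) and `percent`
(columns closed to 100, the form in which mock-control tables are
conventionally printed). Conversion is always explicit; `toRelative()`
refuses already-relative input so an accidental double normalisation cannot
pass silently.

## Preprocessing

**Contaminant filtering** (`decontaminate()`) is performed separately for
each plate against that plate's own negative controls, and is refused —
never silently skipped — when a plate has none. Two per-taxon scores are
computed on a p-value-like scale (small = contaminant-like):

* *prevalence*: a one-sided Fisher exact test on the 2 × 2
  presence/absence table (taxon × negative/real sample), alternative
  "enriched in negatives" — the small-sample-safe choice given the handful
  of negatives a plate carries, and the package's own instantiation of the
  widely used combined frequency/prevalence approach with its conventional
  0.1 threshold.
* *frequency* (only when DNA concentrations are available): a one-sided
  Spearman test of the taxon's within-sample relative frequency against
  inverse DNA concentration, the rank-robust expression of "contaminants
  make up more of low-input libraries".

When both exist they are combined by Fisher's method; a taxon is removed
when the combined score falls below the threshold (default 0.1, applied to
the combined score). Presence defaults to count > 0 with a configurable
floor. Filtering is row deletion: remaining values are untouched, and a
second pass on filtered output flags nothing new. The pipeline fixes the
order decontaminate → normalise → convert to relative; the alternative
order is not meaningfully different for these statistics but fixing one
keeps runs comparable.

**Median library-size normalisation** (`normalizeMedianLibrary()`) rescales
every sample to the median library size, preserving within-sample
proportions exactly. No batch-effect correction is offered: plate-wise
decontamination already operates per batch, and correcting twice is
over-correction.

## Mock-community evaluation

Scoring is strict and species-rank-only. Against a `MockReference` (the
8-species ZymoBIOMICS standard ships as `zymoReference()`, with aliases for
classifier-era synonymy such as *Lactobacillus* → *Limosilactobacillus
fermentum* and *Escherichia coli* → *Escherichia/Shigella coli*):

* a reference species is **detected** iff a species-rank taxon
  alias-resolves to it with abundance above the floor (default 0 — rare
  taxa are kept; raising the floor is exposed because dropping rare taxa is
  known to flatter precision, and scoring with it left at 0 is the stricter,
  more honest default);
* species-rank taxa resolving to nothing are **false positives**;
* a species missed at species rank whose genus appears at genus rank is a
  **genus rescue** — reported, but never counted as a true positive.

From the confusion counts: precision = TP/(TP+FP), sensitivity =
TP/(TP+FN), F-score = their harmonic mean (0 when both are 0; precision of
an empty profile is reported as 0 with an explicit flag). Abundance
accuracy is summarised by observed/expected (O/E) ratios per species —
observed percent divided by theoretical percent, with non-detections
contributing exactly 0 and zeros included in the median and range — and by
the percent of each control's profile correctly classified (the sum of
species-rank abundances resolving to reference species). Two identities tie
these together and are enforced in tests: percent correct plus the residual
"Other" mass closes to 100, and Σ ratio × theoretical percent equals
percent correct.

Full precision is kept internally; rendering rounds half-up to 2 decimals
only at the report boundary (`formatHalfUp()`), which is what makes the
published tables regenerable cell-for-cell from their own count rows.

## Diversity and reproducibility

Alpha diversity (per sample, at a chosen rank, unresolved taxa pooled and
excluded): observed richness, Shannon's index (natural log by default; the
base is a parameter) and Simpson's index in its Gini-Simpson form 1 − Σp².
Beta diversity: Bray-Curtis on relative abundances and Jaccard on
presence/absence — the presence-based variant, not the abundance-weighted
one, matching how the distinction between them is usually drawn.
Computation is delegated to vegan; the tests verify both against direct
formula evaluation.

Paired comparisons use the two-sided Wilcoxon signed-rank test with a 95%
Hodges-Lehmann interval from Walsh averages. Zero differences are dropped
(Wilcoxon's original treatment); the exact distribution is used up to 25
non-zero untied differences, the normal approximation with continuity
correction otherwise; an all-zero difference vector returns a flagged
degenerate result (p = 1, interval collapsed at 0) instead of an error.

Reproducibility of beta diversity uses a distance-based intraclass
correlation coefficient. The estimator is method-of-moments on squared
distances:

dICC = 1 − MS~w~ / MS~t~,

with MS~w~ the mean squared distance within designated pairs and MS~t~ the
mean squared distance over all cross-pair sample pairs. The source
literature for dICC does not print a closed formula, so this estimator is
pinned by its anchor behaviour instead: it is exactly 1 for perfect
duplicates, centred at 0 under random re-pairing, and with Euclidean
distances on univariate Gaussian data it reduces to the classical ICC(1),
estimating σ²~b~/(σ²~b~+σ²~w~). Estimates may go slightly negative by
sampling noise and are reported unclipped. Interpretation uses the standard
reliability bands: < 0.5 poor, 0.5–0.75 moderate, ≥ 0.75 good. dICC point
values published for real replicate datasets can only be recomputed from
those datasets; here such values serve only to check the qualitative bands,
while the estimator itself is validated by the property tests above.

## The synthetic-data generator

`syntheticSpec()` parameterises a seeded generator that stands in for
sequenced samples. Its defaults describe one realistic benchmarking
campaign and were chosen once, up front:

* the 8-species reference; compositional noise as a log-normal perturbation
  with sd 1/√concentration followed by closure (concentration 100 ≈ the
  spread the printed mock-control columns show around theory; log-normal
  rather than Dirichlet so the σ parameters map monotonically onto
  Bray-Curtis spread, which the dICC recovery tests need);
* dropout probability 0.15 for the two hard-to-lyse gram-positive species,
  *Bacillus subtilis* rescued at genus rank (its mass stays at
  `g__Bacillus;s__`, so percent correct drops as observed) and *Listeria
  monocytogenes* lost outright;
* about 3 spurious taxa per control (Poisson), drawn from a fixed 50-name
  decoy catalogue at 0.01–0.5% each, keeping outputs human-readable and
  seeds portable;
* libraries of 50,000–200,000 reads;
* replicate pairs from a Gaussian variance-components model on log
  abundances (17 pairs, 50 taxa, σ~b~ = 1, σ~w~ = 0.25), closed by softmax
  with a 0.5% detection limit so presence/absence metrics stay informative;
  the closed-form truth σ²~b~/(σ²~b~+σ²~w~) is recorded, and holds exactly
  for Euclidean distances on the latent log profiles (also returned);
* plates of 12 real samples, 4 negatives and both mock controls, with 3
  planted reagent contaminants at 10× negative-control enrichment. Each
  contaminant is present in every negative and in a fixed 25% of real
  samples (which samples is random; how many is not), and community taxa
  are present in every real sample by construction — so exact recovery at
  threshold 0.1, and zero false flags without a plan, are properties of the
  design rather than of a lucky seed.

Identical spec + seed gives bit-identical TSV output; each simulated object
derives its own RNG stream from the seed and its identifier.

What the generator does **not** emulate: read-level error (chimeras, PCR
substitution), taxonomic misassignment between related species,
depth-dependent detection, overdispersion beyond log-normal, or correlated
community structure. Passing tests therefore demonstrate that the
statistics are computed correctly and behave as theory predicts on data
with known truth — not that any particular wet-lab protocol is accurate.

## Numerical choices and degenerate inputs

* Column closure tolerances: 1e-6 for relative tables read from files
  (1e-9 is enforced on `toRelative()` output), 0.05 for percent tables
  (printed to 2 decimals).
* Medians are the standard sample median (mean of the middle two for even
  n); zeros from non-detection are included.
* Rounding at the report boundary is half-up (0.875 → 0.88, 0.125 → 0.13),
  not banker's.
* Zero-total samples are errors everywhere they would silently propagate
  (normalisation, relative conversion, alpha diversity at a rank).
* dICC with an all-zero cross-pair distance matrix (e.g. Jaccard on fully
  dense profiles) is an informative error, not NaN.
* Fisher's-method combination clamps p at 1e-300 to avoid log(0).

## Problem sizes

The test suite and the acceptance script run at desk scale: the published
tables are 8 species × 7 controls; property tests use 10–50 pairs, 30–50
taxa, 1000 null simulations for the type-I-error check and a 3 × 3
variance grid × 20 seeds for dICC recovery. The full suite completes in
well under a minute.

## Limitations

Scoring is presence-based and strict at species rank, so one spurious taxon
at 0.01% costs as much precision as one at 10% — read O/E ratios alongside
F-scores. The dICC estimator is one defensible member of a family; with
more than two replicates per subject it would need a design-weighted
generalisation, which is out of scope here, as are phylogeny-aware metrics,
rarefaction, and batch-effect correction.
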