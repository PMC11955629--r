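# mockbench

Benchmarking toolkit for **species-level 16S rRNA amplicon profiles**
evaluated against defined mock communities, written for labs validating a
sequencing-plus-classification protocol (and for anyone re-analysing such
validation data). Its input is a taxa-by-sample abundance table with lineage
strings — the output of an upstream read-processing pipeline — not raw
reads.

## What it computes

Given observed profiles of a mock community with known ("theoretical")
composition, such as the 8-species ZymoBIOMICS standard:

* **Classification performance.** With TP = expected species detected at
  species rank, FP = species-rank taxa matching no expected species and
  FN = expected species missed:

  precision = TP/(TP+FP), sensitivity = TP/(TP+FN),
  F = 2·precision·sensitivity/(precision+sensitivity).

  Species missed at species rank but seen at genus rank ("genus rescues")
  are reported and never counted as TP.
* **Abundance accuracy.** Observed/expected ratios per species,
  O/E = observed % / theoretical %, summarised as median (range) across
  controls with non-detections contributing 0; and the percent of each
  control correctly classified (sum of species-rank abundance over expected
  species).
* **Preprocessing.** Plate-wise contaminant filtering against negative
  controls (one-sided Fisher exact prevalence test, optional Spearman
  frequency test against inverse DNA concentration, combined by Fisher's
  method, threshold 0.1) and median library-size normalisation.
* **Diversity.** Observed richness, Shannon (−Σp ln p) and Gini-Simpson
  (1−Σp²) alpha diversity; Bray-Curtis and presence/absence Jaccard
  distances.
* **Reproducibility.** Paired Wilcoxon signed-rank tests with 95%
  Hodges-Lehmann intervals for alpha diversity of replicate pairs, and a
  distance-based intraclass correlation coefficient (dICC) for beta
  diversity: dICC = 1 − MS_w/MS_t, the mean squared within-pair distance
  over the mean squared cross-pair distance (1 = perfect duplicates, ~0 =
  unrelated pairing, <0.5 poor / 0.5–0.75 moderate / ≥0.75 good).
* **Synthetic data.** A seeded generator producing mock-control profiles
  with controlled error modes (compositional noise, species dropout with
  genus rescue, spurious taxa), replicate pairs with known ground-truth
  dICC, and plates with planted contaminants — every statistic above can be
  exercised against known truth.

The central container extends Bioconductor's `SummarizedExperiment`; I/O is
plain TSV.

## Worked example

Score the shipped extraction-control table (8 expected species + residual
"Other", seven controls) against the Zymo reference:

```r
library(mockbench)
ref <- zymoReference()
tab <- readAbundanceTable(system.file("extdata",
  "mock_extraction_observed.tsv", package = "mockbench"))

oe <- oeRatios(tab, ref)
data.frame(species = oe$species_label,
           oe = formatOERecord(oe$median_ratio, oe$min_ratio, oe$max_ratio))
#>                        species               oe
#>  Limosilactobacillus fermentum 0.98 (0.90–1.01)
#>              Bacillus subtilis 1.07 (0.00–1.13)
#>          Staphylococcus aureus 0.69 (0.59–0.74)
#>         Listeria monocytogenes 0.32 (0.00–0.35)
#>            Salmonella enterica 1.69 (1.05–1.96)
#>      Escherichia/Shigella coli 1.87 (1.69–2.04)
#>          Enterococcus faecalis 0.50 (0.46–0.54)
#>         Pseudomonas aeruginosa 1.55 (0.81–1.85)

percentCorrect(tab, ref, "R1P1Zymoex")
#> [1] 80.84
```

An O/E median of 1 is unbiased recovery: here *E. coli* and *S. enterica*
are over-recovered (≈1.9×, 1.7×) while *L. monocytogenes* comes back at a
third of its expected abundance and drops out of one control entirely — the
classic gram-positive lysis signature. 80.84% of the first control's
profile is correctly classified at species rank.

Performance scores from confusion counts, e.g. a control with 7 of 8
species detected and 15 false positives:

```r
performance(confusionCounts(7, 15, 1))
#> PerformanceScores: precision=0.3182 sensitivity=0.8750 F=0.4667
```

Reproducibility on synthetic replicate pairs with known truth:

```r
sim <- simulatePairs(syntheticSpec(seed = 1))   # 17 pairs, truth 0.941
res <- dicc(betaDiversity(sim$table, "bray_curtis"), sim$design)
sprintf("dICC = %.3f (%s)", res$dicc, interpretDicc(res))
#> [1] "dICC = 0.928 (good)"
```

A command-line front end over the same functions ships as
`inst/scripts/mockbench` (subcommands `simulate`, `decontam`, `diversity`,
`eval-mocks`, `repro`).

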