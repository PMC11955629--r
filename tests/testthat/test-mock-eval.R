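ref <- zymoReference()

## A perfect single-control profile at the theoretical composition.
perfect_profile <- function(id = "ctl") {
  theo <- theoreticalPercent(ref)
  lin <- vapply(names(theo), mockbench:::.speciesLineage, "")
  make_table(matrix(theo / 100, ncol = 1), mode = "relative",
             lineages = lin, sample_ids = id)
}

test_that("the shipped reference matches the 8-species standard", {
  expect_identical(length(referenceSpecies(ref)), 8L)
  expect_equal(sum(theoreticalPercent(ref)), 100, tolerance = 0.005)
  expect_identical(unname(resolveAlias(ref, "Escherichia coli")),
                   "Escherichia/Shigella coli")
  expect_identical(unname(resolveAlias(ref, "Lactobacillus fermentum")),
                   "Limosilactobacillus fermentum")
  expect_true(is.na(resolveAlias(ref, "Cutibacterium acnes")))
})

test_that("species matching separates detected, spurious and genus rescues", {
  at <- perfect_profile()
  m <- matchSpecies(at, ref, "ctl")
  expect_setequal(m$detected, referenceSpecies(ref))
  expect_length(m$spurious, 0)
  expect_length(m$genus_rescues, 0)

  # B. subtilis present only at genus rank -> missed but genus-rescued
  theo <- theoreticalPercent(ref)
  lin <- vapply(names(theo), mockbench:::.speciesLineage, "")
  lin[["Bacillus subtilis"]] <- "g__Bacillus;s__"
  at2 <- make_table(matrix(theo / 100, ncol = 1), mode = "relative",
                    lineages = lin, sample_ids = "ctl")
  m2 <- matchSpecies(at2, ref, "ctl")
  expect_false("Bacillus subtilis" %in% m2$detected)
  expect_identical(m2$genus_rescues, "Bacillus subtilis")
  expect_length(m2$spurious, 0)

  # an extra non-reference species at 0.3% is spurious at floor 0
  vals <- c(theo / sum(theo) * 0.997, 0.003)
  at3 <- make_table(matrix(vals, ncol = 1), mode = "relative",
                    lineages = c(vapply(names(theo),
                                        mockbench:::.speciesLineage, ""),
                                 "g__Cutibacterium;s__acnes"),
                    sample_ids = "ctl")
  m3 <- matchSpecies(at3, ref, "ctl", floor = 0)
  expect_length(m3$spurious, 1)
  expect_match(m3$spurious, "Cutibacterium")
  # ... and drops below a 1% floor
  m4 <- matchSpecies(at3, ref, "ctl", floor = 0.01)
  expect_length(m4$spurious, 0)

  expect_error(matchSpecies(at, ref, "nope"), "unknown control")
})

test_that("confusion counts follow the set sizes", {
  cc <- confusion(referenceSpecies(ref)[1:7], sprintf("fp%d", 1:15), ref)
  expect_identical(c(cc@tp, cc@fp, cc@fn), c(7L, 15L, 1L))
  cc <- confusion(referenceSpecies(ref), character(0), ref)
  expect_identical(c(cc@tp, cc@fp, cc@fn), c(8L, 0L, 0L))
  cc <- confusion(character(0), sprintf("fp%d", 1:3), ref)
  expect_identical(c(cc@tp, cc@fp, cc@fn), c(0L, 3L, 8L))
  # tp + fn always equals the reference size
  expect_identical(cc@tp + cc@fn, 8L)
})

test_that("performance scores reproduce the published per-control cells", {
  sc <- performance(confusionCounts(7, 15, 1))
  expect_identical(formatHalfUp(c(sc@precision, sc@sensitivity, sc@f_score)),
                   c("0.32", "0.88", "0.47"))
  sc <- performance(confusionCounts(8, 0, 0))
  expect_equal(c(sc@precision, sc@sensitivity, sc@f_score), c(1, 1, 1))
  sc <- performance(confusionCounts(8, 8, 0))
  expect_identical(formatHalfUp(c(sc@precision, sc@sensitivity, sc@f_score)),
                   c("0.50", "1.00", "0.67"))
  # harmonic-mean relation and bounds
  expect_equal(sc@f_score,
               2 * sc@precision * sc@sensitivity /
                 (sc@precision + sc@sensitivity),
               tolerance = 1e-12)
  expect_gte(sc@f_score, min(sc@precision, sc@sensitivity))
  expect_lte(sc@f_score, max(sc@precision, sc@sensitivity))
})

test_that("performance is scale-free and flags undefined precision", {
  a <- performance(confusionCounts(3, 6, 2))
  b <- performance(confusionCounts(9, 18, 6))
  expect_equal(c(a@precision, a@sensitivity, a@f_score),
               c(b@precision, b@sensitivity, b@f_score))
  u <- performance(confusionCounts(0, 0, 8))
  expect_true(u@precision_undefined)
  expect_identical(u@precision, 0)
  expect_identical(u@f_score, 0)
  expect_error(performance(confusionCounts(0, 0, 0)), "all zero")
})

test_that("O/E ratios on the published extraction controls hit the printed cells", {
  at <- readAbundanceTable(ext_path("mock_extraction_observed.tsv"))
  oe <- oeRatios(at, ref)
  rendered <- stats::setNames(
    formatOERecord(oe$median_ratio, oe$min_ratio, oe$max_ratio),
    oe$species_label)
  expect_identical(rendered[["Bacillus subtilis"]], "1.07 (0.00–1.13)")
  expect_identical(rendered[["Listeria monocytogenes"]], "0.32 (0.00–0.35)")
})

test_that("O/E ratio of an exactly-theoretical profile is identically 1", {
  at <- perfect_profile()
  oe <- oeRatios(at, ref)
  expect_equal(oe$median_ratio, rep(1, 8), tolerance = 1e-12)
  expect_equal(oe$min_ratio, oe$max_ratio, tolerance = 1e-12)
})

test_that("sum of ratio x theoretical percent equals percent correct", {
  sim <- simulateMockControls(syntheticSpec(seed = 31),
                              sprintf("c%d", 1:5))
  oe <- oeRatios(sim$table, ref)
  ratios <- attr(oe, "ratios")
  theo <- theoreticalPercent(ref)[rownames(ratios)]
  for (id in sampleIDs(sim$table)) {
    expect_equal(sum(ratios[, id] * theo),
                 percentCorrect(sim$table, ref, id), tolerance = 1e-9)
  }
})

test_that("percent correct matches the published exact columns", {
  ext <- readAbundanceTable(ext_path("mock_extraction_observed.tsv"))
  expect_equal(percentCorrect(ext, ref, "R1P1Zymoex"), 80.84,
               tolerance = 1e-9)
  seq_ <- readAbundanceTable(ext_path("mock_sequencing_observed.tsv"))
  expect_equal(percentCorrect(seq_, ref, "R1P1Zymoseq"), 99.58,
               tolerance = 1e-9)
  expect_equal(percentCorrect(perfect_profile(), ref, "ctl"), 100,
               tolerance = 1e-9)
})

test_that("percent correct plus the residual closes to 100", {
  at <- readAbundanceTable(ext_path("mock_extraction_observed.tsv"))
  other <- abundances(at)[is.na(
    SummarizedExperiment::rowData(at)$resolved_rank), ]
  for (id in sampleIDs(at))
    expect_equal(percentCorrect(at, ref, id) + other[[id]], 100,
                 tolerance = 0.02)
})

test_that("aggregation returns the F-score median and range", {
  reports <- lapply(list(c(7, 15, 1), c(8, 3, 0), c(8, 0, 0)), function(v)
    list(control_id = paste(v, collapse = "-"),
         counts = confusionCounts(v[1], v[2], v[3]),
         scores = performance(confusionCounts(v[1], v[2], v[3]))))
  agg <- aggregateControls(reports)
  expect_identical(agg$n, 3L)
  expect_equal(agg$f_median, performance(confusionCounts(8, 3, 0))@f_score)
  expect_equal(agg$f_range,
               c(performance(confusionCounts(7, 15, 1))@f_score, 1))
  one <- aggregateControls(reports[1])
  expect_equal(one$f_median, reports[[1]]$scores@f_score)
})

test_that("genus rescues are reported but never counted as true positives", {
  theo <- theoreticalPercent(ref)
  lin <- vapply(names(theo), mockbench:::.speciesLineage, "")
  lin[["Bacillus subtilis"]] <- "g__Bacillus;s__"
  at <- make_table(matrix(theo / 100, ncol = 1), mode = "relative",
                   lineages = lin, sample_ids = "ctl")
  rep <- evaluateMockControl(at, ref, "ctl")
  expect_identical(rep$counts@tp, 7L)
  expect_identical(rep$counts@fn, 1L)
  expect_identical(rep$genus_rescues, "Bacillus subtilis")
  # the genus-level mass is excluded from percent correct
  expect_lt(rep$percent_correct, 100 - 17)
})
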