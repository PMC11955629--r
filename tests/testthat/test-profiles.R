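test_that("lineage strings parse to the right ranks and labels", {
  lin <- parseLineage("g__Bacillus;s__")
  expect_identical(resolvedRank(lin), "genus")
  expect_identical(lin@ranks[["genus"]], "Bacillus")

  lin <- parseLineage("g__Escherichia/Shigella;s__coli")
  expect_identical(resolvedRank(lin), "species")
  expect_identical(speciesLabel(lin), "Escherichia/Shigella coli")

  lin <- parseLineage("")
  expect_true(is.na(resolvedRank(lin)))
  expect_true(is.na(speciesLabel(lin)))

  # prefix case and surrounding whitespace are normalised
  lin <- parseLineage(" K__Bacteria ; G__Listeria; s__monocytogenes ")
  expect_identical(lin@ranks[["kingdom"]], "Bacteria")
  expect_identical(speciesLabel(lin), "Listeria monocytogenes")

  # a species field already carrying the binomial is used verbatim
  lin <- parseLineage("s__Cutibacterium acnes")
  expect_identical(speciesLabel(lin), "Cutibacterium acnes")
  expect_true(lin@rank_skipped)
})

test_that("malformed lineage tokens are rejected with the offending token", {
  expect_error(parseLineage("g__Bacillus;subtilis"), "subtilis")
  expect_error(parseLineage("x__Foo"), "x__Foo")
  expect_error(parseLineage("g__A;g__B"), "duplicate rank")
})

test_that("parse and format are mutually inverse over random rank subsets", {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  set.seed(42)
  for (i in 1:50) {
    filled <- sample(c(TRUE, FALSE), 7, replace = TRUE)
    values <- ifelse(filled, sprintf("Taxon%d_%d", i, 1:7), "")
    lin <- mockbench:::.newLineage(stats::setNames(values, ranks))
    expect_identical(parseLineage(formatLineage(lin))@ranks, lin@ranks)
  }
})

test_that("abundance tables read from TSV with mode auto-detection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lineage\ts1\ts2",
               "g__A;s__a\t5\t1",
               "g__B;s__b\t3\t0",
               "g__C;s__c\t2\t9"), path)
  at <- readAbundanceTable(path)
  expect_s4_class(at, "AbundanceTable")
  expect_identical(abundanceMode(at), "counts")
  expect_identical(dim(abundances(at)), c(3L, 2L))

  # negative cell is rejected with its location
  writeLines(c("lineage\ts1\ts2",
               "g__A;s__a\t5\t1",
               "g__B;s__b\t-1\t0"), path)
  expect_error(readAbundanceTable(path), "row 2.*s1")

  # duplicate lineages collide on canonical identity
  writeLines(c("lineage\ts1",
               "g__A;s__a\t5",
               "g__A;s__a\t3"), path)
  expect_error(readAbundanceTable(path), "duplicate lineage")
})

test_that("the published extraction-control fixture parses as percentages", {
  at <- readAbundanceTable(ext_path("mock_extraction_observed.tsv"))
  expect_identical(abundanceMode(at), "percent")
  expect_identical(ncol(abundances(at)), 7L)
  expect_true(all(abs(colSums(abundances(at)) - 100) <= 0.02))
})

test_that("read-write-read round trip is bit-exact", {
  set.seed(7)
  at <- make_table(matrix(rexp(12) * 1000, 4, 3), mode = "counts")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeAbundanceTable(at, p1)
  r1 <- readAbundanceTable(p1, mode_hint = "counts")
  expect_identical(abundances(r1), abundances(at))
  expect_identical(rownames(r1), rownames(at))
  writeAbundanceTable(r1, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("toRelative closes columns and refuses double normalisation", {
  at <- make_table(matrix(c(50, 50, 80, 15), 2))
  rel <- toRelative(at)
  expect_identical(abundanceMode(rel), "relative")
  expect_equal(abundances(rel)[, 1], c(0.5, 0.5), ignore_attr = TRUE)
  expect_true(all(abs(colSums(abundances(rel)) - 1) < 1e-9))
  expect_error(toRelative(rel), "already")

  at3 <- make_table(matrix(c(80, 15, 5), 3))
  expect_equal(abundances(toRelative(at3))[, 1], c(0.80, 0.15, 0.05),
               ignore_attr = TRUE)

  # relative conversion preserves within-sample rank order
  set.seed(11)
  m <- matrix(rpois(40, 30), 8, 5)
  ranks_before <- apply(m, 2, rank)
  ranks_after <- apply(abundances(toRelative(make_table(m))), 2, rank)
  expect_equal(ranks_after, ranks_before, ignore_attr = TRUE)

  expect_error(toRelative(make_table(matrix(c(1, 0, 0, 0), 2))),
               "zero total")
})

test_that("sample metadata validation enforces the pairing contract", {
  meta <- data.frame(sample_id = c("a", "b", "c", "n1"),
                     run = "R1", plate = "P1",
                     control_role = c("none", "none", "none", "negative"),
                     replicate_pair_id = c("p1", "p1", NA, NA),
                     stringsAsFactors = FALSE)
  expect_silent(validateSampleMetadata(meta))

  bad <- meta
  bad$replicate_pair_id <- c("p1", "p1", "p1", NA)
  expect_error(validateSampleMetadata(bad), "exactly two")

  bad <- meta
  bad$replicate_pair_id <- c("p1", NA, NA, "p1")
  expect_error(validateSampleMetadata(bad), "negative controls")

  bad <- meta
  bad$control_role[1] <- "mock"
  expect_error(validateSampleMetadata(bad), "control_role")
})

test_that("collapseAtRank pools taxa and drops the unassigned bin", {
  at <- make_table(matrix(c(10, 20, 30, 40), 4, 1),
                   lineages = c("g__A;s__x", "g__A;s__y", "g__A;s__",
                                ""))
  sp <- collapseAtRank(at, "species")
  expect_identical(sort(rownames(sp)), c("A x", "A y"))
  gen <- collapseAtRank(at, "genus")
  expect_equal(gen["A", 1], 60)
  gen_all <- collapseAtRank(at, "genus", include_unassigned = TRUE)
  expect_equal(gen_all["unassigned", 1], 40)
})
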