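test_that("median library-size normalisation equalises totals", {
  at <- make_table(matrix(c(60, 40, 150, 50, 100, 200), 2, 3))
  norm <- normalizeMedianLibrary(at)      # totals 100, 200, 300 -> all 200
  expect_equal(unname(colSums(abundances(norm))), c(200, 200, 200))

  one <- make_table(matrix(c(70, 7), 2, 1))
  expect_equal(abundances(normalizeMedianLibrary(one)),
               abundances(one))           # median of one total: unchanged

  two <- make_table(matrix(c(6, 4, 600, 400), 2, 2))
  norm2 <- normalizeMedianLibrary(two)    # totals (10, 1000) -> both 505
  expect_equal(unname(colSums(abundances(norm2))), c(505, 505))
  expect_equal(abundances(norm2)[, 1], abundances(two)[, 1] * 50.5,
               ignore_attr = TRUE)
  expect_equal(abundances(norm2)[, 2], abundances(two)[, 2] * 0.505,
               ignore_attr = TRUE)
})

test_that("normalisation preserves within-sample proportions exactly", {
  set.seed(5)
  at <- make_table(matrix(rpois(60, 50) + 1, 10, 6))
  norm <- normalizeMedianLibrary(at)
  prop_before <- sweep(abundances(at), 2, colSums(abundances(at)), "/")
  prop_after <- sweep(abundances(norm), 2, colSums(abundances(norm)), "/")
  expect_equal(prop_after, prop_before, tolerance = 1e-12)
})

test_that("normalisation rejects zero-total samples and non-count tables", {
  at <- make_table(matrix(c(5, 5, 0, 0), 2, 2))
  expect_error(normalizeMedianLibrary(at), "zero total")
  expect_error(normalizeMedianLibrary(toRelative(make_table(matrix(1:4, 2)))),
               "counts")
})

test_that("extreme prevalence patterns are scored as expected", {
  # 2 taxa x (3 negatives + 6 real): taxon 1 only in negatives, taxon 2 only
  # in real samples
  m <- rbind(c(50, 40, 60, 0, 0, 0, 0, 0, 0),
             c(0, 0, 0, 100, 90, 110, 100, 95, 105),
             c(5, 4, 6, 80, 70, 90, 85, 75, 95))
  ids <- c(sprintf("n%d", 1:3), sprintf("r%d", 1:6))
  colnames(m) <- ids
  at <- make_table(m, sample_ids = ids)
  meta <- data.frame(sample_id = ids, run = "R1", plate = "P1",
                     control_role = c(rep("negative", 3), rep("none", 6)),
                     stringsAsFactors = FALSE)
  res <- decontaminate(at, meta, plate = "P1", threshold = 0.1)
  sc <- res$scores
  expect_true(sc$is_contaminant[1])        # negatives-only taxon removed
  expect_false(sc$is_contaminant[2])       # reals-only taxon kept
  expect_false(sc$is_contaminant[3])       # ubiquitous taxon kept
  expect_lt(sc$prevalence_score[1], 0.1)
  expect_equal(sc$prevalence_score[2], 1)
  # no concentrations supplied: combined score equals the prevalence score
  expect_true(all(is.na(sc$frequency_score)))
  expect_identical(sc$combined_score, sc$prevalence_score)
  expect_identical(nrow(res$table), 2L)
})

test_that("planted contaminants are recovered exactly on a synthetic plate", {
  pl <- simulatePlate(syntheticSpec(seed = 101))
  res <- decontaminate(pl$table, pl$meta, plate = "P1", threshold = 0.1)
  flagged <- res$scores$taxon[res$scores$is_contaminant]
  expect_setequal(flagged, pl$truth$contaminants)

  # independent oracle: recompute every per-taxon 2x2 Fisher table by hand
  neg <- pl$meta$sample_id[pl$meta$control_role == "negative"]
  real <- pl$meta$sample_id[pl$meta$control_role != "negative"]
  m <- abundances(pl$table)
  oracle <- vapply(rownames(m), function(tx) {
    a <- sum(m[tx, neg] > 0); c_ <- sum(m[tx, real] > 0)
    stats::fisher.test(cbind(c(a, length(neg) - a),
                             c(c_, length(real) - c_)),
                       alternative = "greater")$p.value < 0.1
  }, logical(1))
  expect_setequal(rownames(m)[oracle], flagged)
})

test_that("decontamination is idempotent and refuses plates without negatives", {
  pl <- simulatePlate(syntheticSpec(seed = 55))
  res <- decontaminate(pl$table, pl$meta, plate = "P1")
  res2 <- decontaminate(res$table, pl$meta, plate = "P1")
  expect_false(any(res2$scores$is_contaminant))
  expect_identical(abundances(res2$table), abundances(res$table))

  meta_nn <- pl$meta
  meta_nn$control_role[meta_nn$control_role == "negative"] <- "none"
  expect_error(decontaminate(pl$table, meta_nn, plate = "P1"),
               "no negative controls")
  expect_error(decontaminate(pl$table, pl$meta, plate = "P9"), "P9")
})

test_that("frequency scores engage when DNA concentrations are supplied", {
  set.seed(9)
  n_real <- 10
  conc <- seq(2, 20, length.out = n_real)
  # contaminant-like taxon: constant absolute level, so its relative share
  # scales with 1/concentration; genuine taxon scales with concentration
  contam_counts <- rep(200, n_real)
  real_counts <- round(conc * 500)
  m <- rbind(c(rep(150, 2), contam_counts),
             c(rep(5, 2), real_counts))
  ids <- c("n1", "n2", sprintf("r%d", seq_len(n_real)))
  colnames(m) <- ids
  at <- make_table(m, sample_ids = ids)
  meta <- data.frame(sample_id = ids, run = "R1", plate = "P1",
                     control_role = c("negative", "negative",
                                      rep("none", n_real)),
                     dna_concentration = c(NA, NA, conc),
                     stringsAsFactors = FALSE)
  res <- decontaminate(at, meta, plate = "P1", threshold = 0.1)
  sc <- res$scores
  expect_false(any(is.na(sc$frequency_score)))
  expect_lt(sc$frequency_score[1], 0.05)   # share tracks 1/concentration
  expect_gt(sc$frequency_score[2], 0.5)
  expect_true(sc$is_contaminant[1])
  expect_false(sc$is_contaminant[2])
})

test_that("row deletion leaves remaining raw values untouched", {
  pl <- simulatePlate(syntheticSpec(seed = 77))
  res <- decontaminate(pl$table, pl$meta, plate = "P1")
  keep <- setdiff(rownames(pl$table), pl$truth$contaminants)
  expect_identical(abundances(res$table)[keep, ],
                   abundances(pl$table)[keep, sampleIDs(res$table)])
})
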