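# Library analytics: class tables, closed-form estimates, ring census and
# overlap.

test_that("class distribution reproduces the production-run percentages", {
  tab <- class_distribution(counts = production_run_counts$class_saved,
                            unique_counts = production_run_counts$class_unique)
  pct <- stats::setNames(tab$percent, tab$class)
  expect_equal(pct[["Plus"]], 62.61)
  expect_equal(pct[["Neg30"]], 29.52)
  expect_equal(pct[["Neg20"]], 4.70)
  expect_equal(pct[["Neg10"]], 3.13)
  expect_equal(pct[["Neg0"]], 0.03)
  # percentages sum to 100 up to rounding
  expect_lt(abs(sum(tab$percent) - 100), 0.05)
  # cross-class duplicates: unique combined below the per-class sum
  expect_lt(production_run_counts$unique_combined, sum(tab$unique))
})

test_that("degenerate class tables behave", {
  expect_identical(nrow(class_distribution(counts = c(Plus = 0, Neg0 = 0))), 0L)
  one <- class_distribution(counts = c(Plus = 42))
  expect_equal(one$percent, 100)
})

test_that("theoretical maximum and success ratio follow the closed forms", {
  expect_equal(theoretical_max(2, 1), 2)
  expect_equal(theoretical_max(0, 53), 0)
  expect_equal(theoretical_max(10, 3), 150)
  expect_equal(success_ratio(100, 100)$ratio, 1)
  expect_true(is.na(success_ratio(100, 0)$ratio))
  expect_equal(success_ratio(6.165e11, 1748464003)$ratio_display, 350)
})

test_that("SAR-neighbor estimate interpolates between empty and full matrices", {
  # full triangular matrix: every product neighbors all other blocks
  full <- sar_neighbors(100, 0.5 * 100^2)
  expect_equal(full$fill, 1)
  expect_equal(full$mean_neighbors, 100)
  expect_equal(sar_neighbors(100, 0)$mean_neighbors, 0)
  est <- sar_neighbors(production_run_counts$n_bb_matched,
                       production_run_counts$total_saved)
  expect_equal(est$fill, 0.17, tolerance = 0.01)
  expect_equal(est$mean_neighbors, 2.4e4, tolerance = 0.02)
})

test_that("ring systems are connected units of ring atoms and bonds", {
  cen <- ring_system_census(c("c1ccc2ccccc2c1",  # naphthalene: one fused unit
                              "c1ccc(-c2ccccc2)cc1",  # biphenyl: two benzenes
                              "CCCCCC"))         # no rings
  expect_identical(attr(cen, "n_unique"), 2L)
  benzene <- cen$count[cen$system == canonical_smiles("c1ccccc1")]
  expect_identical(benzene, 2L)
  expect_identical(sum(cen$count), 3L)
  # census is invariant to the input atom ordering
  cen2 <- ring_system_census("C1=CC2=CC=CC=C2C=C1")
  cen3 <- ring_system_census("c1ccc2ccccc2c1")
  expect_identical(cen2$system, cen3$system)
})

test_that("overlap recovers a planted shared fraction exactly", {
  run <- sf_small_run()
  keys <- unique(run$records$product_key)
  # plant 10% shared structures in a synthetic reference set
  shared <- keys[seq_len(ceiling(length(keys) * 0.1))]
  reference <- c(shared, paste0("decoy", seq_len(50)))
  ov <- overlap_keys(keys, reference)
  expect_identical(ov$n_intersection, length(shared))
  expect_identical(ov$n_b_only, 50L)
  expect_identical(ov$n_a_only, length(keys) - length(shared))
  # symmetry of the intersection count
  expect_identical(overlap_keys(reference, keys)$n_intersection,
                   ov$n_intersection)
  expect_identical(overlap_keys(letters, LETTERS)$n_intersection, 0L)
})
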