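test_that("the generator plants the advertised structure deterministically", {
  ds <- simulate_pathway_data(17)
  expect_equal(sum(2 + 4 + 6 + 10 + 20 + 40 + 80), 162)
  expect_setequal(ds$truth, c("Two", "Four", "Six", "Ten", "Twenty", "Forty",
                              "Eighty"))
  sizes <- vapply(ds$sets$sets[ds$truth], function(s) length(s$members), integer(1))
  expect_equal(sort(unname(sizes)), c(2, 4, 6, 10, 20, 40, 80))
  bg <- setdiff(names(ds$sets$sets), ds$truth)
  expect_length(bg, 100)
  bg_sizes <- vapply(ds$sets$sets[bg], function(s) length(s$members), integer(1))
  expect_true(all(bg_sizes >= 5 & bg_sizes <= 50))
  expect_equal(nrow(ds$matrix$values), 162 + sum(bg_sizes))
  expect_equal(ncol(ds$matrix$values), 8)
  # rows standardised for input
  expect_lt(max(abs(rowMeans(ds$matrix$values))), 1e-12)
  expect_lt(max(abs(apply(ds$matrix$values, 1, var) - 1)), 1e-12)
  # identical seed, identical dataset; different seed, different data
  ds2 <- simulate_pathway_data(17)
  expect_identical(ds$matrix$values, ds2$matrix$values)
  expect_identical(names(ds$sets$sets), names(ds2$sets$sets))
  expect_false(identical(ds$matrix$values[1, ],
                         simulate_pathway_data(18)$matrix$values[1, ]))
})

test_that("planted changes are detectable at the stated power", {
  frac_de <- function(effect) {
    hits <- total <- 0
    for (s in 301:303) {
      ds <- simulate_pathway_data(s, effect_size = effect)
      fs <- feature_significance(ds$matrix, c("case", "control"))
      # changing features occupy the first 162 rows by construction
      hits <- hits + sum(fs$de[seq_len(162)])
      total <- total + 162
    }
    hits / total
  }
  # strong effects: nearly every changing feature is individually significant
  expect_gt(frac_de(4), 0.90)
  # the calibrated default trades per-feature power for realistic set-level
  # p-value magnitudes; the block structure is still clearly detectable
  expect_gt(frac_de(2.2), 0.60)
  # background features are significant at roughly the nominal rate
  ds <- simulate_pathway_data(304)
  fs <- feature_significance(ds$matrix, c("case", "control"))
  expect_lt(mean(fs$de[-seq_len(162)]), 0.09)
})

test_that("decoy injection follows the rounding rule and touches only changing sets", {
  ds <- simulate_pathway_data(19)
  before <- vapply(ds$sets$sets, function(s) length(s$members), integer(1))
  d50 <- add_decoys(ds, 50)
  after <- vapply(d50$sets$sets, function(s) length(s$members), integer(1))
  expect_equal(after[["Forty"]], 40L + 20L)
  expect_equal(after[["Eighty"]], 80L + 40L)
  # round half away from zero: Two at 25% gains one decoy
  d25 <- add_decoys(ds, 25)
  expect_equal(length(d25$sets$sets$Two$members), 3L)
  # background sets untouched
  bg <- setdiff(names(before), ds$truth)
  expect_equal(after[bg], before[bg])
  # matrix and annotations grew consistently
  expect_equal(nrow(d50$matrix$values), nrow(ds$matrix$values) + 81L)
  expect_equal(nrow(d50$annotations), nrow(ds$annotations) + 81L)
  # level 0 is the identity
  expect_identical(add_decoys(ds, 0), ds)
  # off-grid levels are accepted with a warning
  expect_warning(add_decoys(ds, 30), "outside the standard")
  # decoy features carry no group effect: their per-feature DE rate is nominal
  d1000 <- add_decoys(ds, 1000)
  fs <- feature_significance(d1000$matrix, c("case", "control"))
  decoy_rows <- grepl("^DECOY", fs$feature_id)
  expect_gt(sum(decoy_rows), 1600)
  expect_lt(mean(fs$de[decoy_rows]), 0.09)
})

test_that("feature dropout removes the stated fraction and updates the dataset", {
  ds <- simulate_pathway_data(23)
  expect_identical(drop_features(ds, 0), ds)
  dropped <- drop_features(ds, 0.2)
  expect_lt(nrow(dropped$matrix$values), nrow(ds$matrix$values))
  expect_setequal(dropped$annotations$feature_id, rownames(dropped$matrix$values))
  # sets stay in the database even if emptied; mapping reflects the loss
  expect_equal(length(dropped$sets$sets), length(ds$sets$sets))
  # binomial concentration: mean removed fraction ~ p over many draws
  n_feat <- nrow(ds$matrix$values)
  fracs <- vapply(1:200, function(i) {
    d <- drop_features(ds, 0.2, seed = 5000 + i)
    1 - nrow(d$matrix$values) / n_feat
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.2), 0.02)
  # reproducible given the derived seed
  expect_identical(drop_features(ds, 0.4)$matrix$values,
                   drop_features(ds, 0.4)$matrix$values)
})
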