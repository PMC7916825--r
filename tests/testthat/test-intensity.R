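test_that("imputation fills missing values per factor group", {
  m <- make_raw_matrix()
  out <- impute_missing(m, min_intensity = 5000)
  # all-missing group block -> minimum intensity
  expect_equal(unname(out$values["F1", 1:3]), c(5000, 5000, 5000))
  # partially missing -> mean of observed
  expect_equal(unname(out$values["F2", 1:3]), c(15, 10, 20))
  # fully observed unchanged
  expect_equal(unname(out$values["F3", ]), c(3, 4, 5, 6, 7, 8))
  expect_true(all(out$values > 0))
})

test_that("imputation is idempotent and validates input", {
  m <- make_raw_matrix()
  once <- impute_missing(m)
  twice <- impute_missing(once)
  expect_identical(once$values, twice$values)
  expect_error(impute_missing(m, min_intensity = -1), "positive")
  bad <- m
  bad$values[1, 1] <- -5
  expect_error(impute_missing(bad), "negative")
})

test_that("normalisation gives zero mean, unit variance per feature and group", {
  set.seed(101)
  vals <- matrix(exp(rnorm(40 * 6, 10, 1)), 40, 6,
                 dimnames = list(sprintf("F%02d", 1:40),
                                 c("a1", "a2", "a3", "b1", "b2", "b3")))
  design <- setNames(rep(c("g1", "g2"), each = 3), colnames(vals))
  m <- normalise_intensities(intensity_matrix(vals, design))
  for (g in c("g1", "g2")) {
    block <- m$values[, names(design)[design == g]]
    expect_lt(max(abs(rowMeans(block))), 1e-10)
    expect_lt(max(abs(apply(block, 1, var) - 1)), 1e-10)
  }
  # two-point group standardises to -1 / +1 (sample sd, n - 1 denominator)
  v2 <- matrix(c(exp(1), exp(3), exp(2), exp(5)), 1, 4,
               dimnames = list("F1", c("a1", "a2", "b1", "b2")))
  d2 <- c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2")
  m2 <- normalise_intensities(intensity_matrix(v2, d2))
  expect_equal(unname(m2$values[1, ]), c(-1, 1, -1, 1) / sqrt(2))
})

test_that("zero-variance groups are centred, warned, and never NaN", {
  vals <- matrix(exp(1), 1, 4, dimnames = list("F1", c("a1", "a2", "b1", "b2")))
  vals[1, 3:4] <- c(exp(1), exp(2))
  d <- c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2")
  expect_warning(m <- normalise_intensities(intensity_matrix(vals, d)),
                 "zero-variance")
  expect_equal(unname(m$values[1, 1:2]), c(0, 0))
  expect_false(anyNA(m$values))
  expect_error(normalise_intensities(intensity_matrix(vals - 3, d)), "positive")
})

test_that("whole-row standardisation is available as an alternative scope", {
  set.seed(5)
  vals <- matrix(exp(rnorm(24, 8, 1)), 4, 6,
                 dimnames = list(paste0("F", 1:4),
                                 c("a1", "a2", "a3", "b1", "b2", "b3")))
  d <- setNames(rep(c("g1", "g2"), each = 3), colnames(vals))
  m <- normalise_intensities(intensity_matrix(vals, d), scope = "row")
  expect_lt(max(abs(rowMeans(m$values))), 1e-10)
  expect_lt(max(abs(apply(m$values, 1, var) - 1)), 1e-10)
})

test_that("set submatrix selects all features sharing member formulae", {
  m <- make_raw_matrix()
  ann <- data.frame(feature_id = c("F1", "F2", "F3", "F4"),
                    formula = c("C6H12O6", "C6H12O6", "C5H9NO4", "C3H7NO2"),
                    adduct = "M+H")
  # one formula -> two features
  sub <- build_set_matrix(m, ann, "C6H12O6")
  expect_equal(rownames(sub$values), c("F1", "F2"))
  expect_identical(sub$design, m$design)
  # no mapped members -> empty signal, not an error
  expect_null(build_set_matrix(m, ann, "C10H10"))
  # single match
  expect_equal(rownames(build_set_matrix(m, ann, c("X", "C3H7NO2"))$values), "F4")
  # result rows always a subset of input rows, column order preserved
  sub2 <- build_set_matrix(m, ann, c("C6H12O6", "C5H9NO4"))
  expect_true(all(rownames(sub2$values) %in% rownames(m$values)))
  expect_identical(colnames(sub2$values), colnames(m$values))
})

test_that("intensity/annotation/design readers round-trip and filter adducts", {
  dir <- withr::local_tempdir()
  fx <- write_cli_fixture(dir)
  design <- read_design(fx$design)
  expect_equal(sort(unique(design)), c("case", "control"))
  expect_equal(sum(design == "case"), 4)
  m <- read_intensity_csv(fx$intensity, design)
  expect_equal(dim(m$values), c(30L, 8L))
  expect_true(all(m$values >= 0))  # blanks/NA coerced to zero
  ann <- read_annotations(fx$annotations)
  expect_true(all(ann$adduct %in% c("M+H", "M-H")))
  expect_false("NaCl" %in% ann$formula)  # the M+Na record was dropped
  # unicode minus and decorated adducts normalise
  p <- file.path(dir, "ann2.csv")
  writeLines(c("feature_id,formula,adduct",
               "f1,C2H6O,(M+H)+", "f2,C2H6O,(M−H)−",
               "f3,C2H6O,M+Na"), p)
  a2 <- read_annotations(p)
  expect_equal(a2$adduct, c("M+H", "M-H"))
})

test_that("design problems are caught early", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "design.txt")
  writeLines(c("g1: s1, s2", "g2: s2, s3"), p)
  expect_error(read_design(p), "more than one group")
  vals <- matrix(1, 2, 2, dimnames = list(c("F1", "F2"), c("s1", "s2")))
  expect_error(intensity_matrix(vals, c(s1 = "g1")), "missing from design")
})
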