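toy_design <- function(n_per_group = 4) {
  setNames(rep(c("case", "control"), each = n_per_group),
           c(paste0("c", seq_len(n_per_group)), paste0("k", seq_len(n_per_group))))
}

test_that("activity levels equal the first right singular vector", {
  # rank-1 matrix: closed form
  X <- matrix(rep(c(1, 2, 3, 4), times = 5), 5, 4, byrow = TRUE,
              dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(activity_levels(X)), c(1, 2, 3, 4) / sqrt(30))
  # single feature: the row scaled to unit norm
  X1 <- matrix(c(3, 0, 4, 0), 1, 4, dimnames = list("f", paste0("s", 1:4)))
  expect_equal(unname(activity_levels(X1)), c(3, 0, 4, 0) / 5)
  # random matrices vs an independent eigendecomposition oracle
  set.seed(31)
  for (i in 1:10) {
    X <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(NULL, paste0("s", 1:8)))
    al <- activity_levels(X)
    ev <- eigen(crossprod(X), symmetric = TRUE)$vectors[, 1]
    ev <- ev * sign(ev[which.max(abs(ev))])
    expect_lt(max(abs(unname(al) - ev)), 1e-10)
    expect_equal(sum(al^2), 1)
    expect_gt(al[which.max(abs(al))], 0)  # sign convention
  }
})

test_that("the set t-statistic is a guarded Welch t", {
  d <- toy_design()
  al <- setNames(c(2.1, 1.9, 2.0, 2.0, 1.0, 1.1, 0.9, 1.0), names(d))
  tt <- t.test(al[1:4], al[5:8])$statistic
  expect_equal(set_t_statistic(al, d, c("case", "control")), unname(tt))
  # antisymmetry under swapping the comparison
  expect_equal(set_t_statistic(al, d, c("control", "case")),
               -set_t_statistic(al, d, c("case", "control")))
  # identical groups give zero
  flat <- setNames(rep(1, 8), names(d))
  expect_equal(set_t_statistic(flat, d, c("case", "control")), 0)
  # zero variance with distinct means: large finite sentinel
  sep <- setNames(rep(c(2, 1), each = 4), names(d))
  expect_equal(set_t_statistic(sep, d, c("case", "control")), 1e6)
  # pooled-variance flavour matches t.test(var.equal = TRUE)
  tp <- t.test(al[1:4], al[5:8], var.equal = TRUE)$statistic
  expect_equal(set_t_statistic(al, d, c("case", "control"), var_equal = TRUE),
               unname(tp))
})

test_that("the permutation null is reproducible and internally consistent", {
  d <- toy_design()
  set.seed(12)
  als <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, names(d)))
  n1 <- permutation_null(als, d, c("case", "control"), n_perm = 200, seed = 5)
  n2 <- permutation_null(als, d, c("case", "control"), n_perm = 200, seed = 5)
  expect_identical(n1$min_t, n2$min_t)
  expect_identical(n1$t_perm, n2$t_perm)
  expect_true(all(n1$min_t <= n1$max_t))
  expect_equal(dim(n1$t_perm), c(20L, 200L))
  expect_error(permutation_null(als, d, c("case", "control"), n_perm = 50, seed = 1),
               ">= 100")
  expect_error(permutation_null(als, d, c("case", "control"), n_perm = 200),
               "seed")
})

test_that("null data gives central observed t and calibrated per-set p-values", {
  d <- toy_design()
  set.seed(88)
  als <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, names(d)))
  nl <- permutation_null(als, d, c("case", "control"), n_perm = 500, seed = 9)
  tobs <- apply(als, 1, function(a) {
    set_t_statistic(setNames(a, names(d)), d, c("case", "control"))
  })
  p_per_set <- vapply(seq_len(50), function(i) {
    tp <- nl$t_perm[i, ]
    min(1, 2 * min((1 + sum(tp >= tobs[i])) / 501, (1 + sum(tp <= tobs[i])) / 501))
  }, numeric(1))
  expect_gt(mean(p_per_set > 0.05), 0.85)
})

test_that("ranked results are deterministic and order-invariant", {
  ds <- simulate_pathway_data(140, n_background = 20)
  comparison <- c("case", "control")
  r1 <- run_mplage(ds$matrix, ds$sets, ds$annotations, comparison,
                   n_perm = 300, seed = 21)
  r2 <- run_mplage(ds$matrix, ds$sets, ds$annotations, comparison,
                   n_perm = 300, seed = 21)
  expect_identical(r1$p_value, r2$p_value)
  # shuffling the input sample columns (design follows) changes nothing
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  m_shuf <- intensity_matrix(ds$matrix$values[, perm],
                             ds$matrix$design[perm])
  r3 <- run_mplage(m_shuf, ds$sets, ds$annotations, comparison,
                   n_perm = 300, seed = 21)
  expect_equal(pv(r3)[names(pv(r1))], pv(r1))
  # ranked ascending by p, ties by set_id
  expect_true(!is.unsorted(r1$p_value))
  expect_equal(r1$rank, seq_len(nrow(r1)))
  # planted pathways dominate the top of the ranking
  expect_true(all(c("Eighty", "Forty", "Twenty") %in% r1$set_id[1:6]))
})

test_that("per-set scope flips tails exactly under an AL sign flip", {
  d <- toy_design()
  set.seed(4)
  als <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, names(d)))
  nl <- permutation_null(als, d, c("case", "control"), n_perm = 200, seed = 2)
  nl_neg <- permutation_null(-als, d, c("case", "control"), n_perm = 200, seed = 2)
  expect_equal(nl_neg$t_perm, -nl$t_perm)
  # two-sided per-set p identical for al and -al
  t1 <- apply(als, 1, function(a) set_t_statistic(setNames(a, names(d)), d,
                                                  c("case", "control")))
  p <- function(tp, t) min(1, 2 * min((1 + sum(tp >= t)) / 201,
                                      (1 + sum(tp <= t)) / 201))
  p_pos <- vapply(1:10, function(i) p(nl$t_perm[i, ], t1[i]), numeric(1))
  p_neg <- vapply(1:10, function(i) p(nl_neg$t_perm[i, ], -t1[i]), numeric(1))
  expect_equal(p_pos, p_neg)
})

test_that("unscoreable sets are skipped with reasons, constant sets flagged p = 1", {
  ds <- simulate_pathway_data(3, n_background = 5)
  # add a set whose formulae are absent and a single-feature set
  sets <- ds$sets$sets
  sets[["ghost"]] <- metabolite_set("ghost", "ghost", "ZZZ999", "formula")
  sets[["lonely"]] <- metabolite_set("lonely", "lonely",
                                     ds$annotations$formula[1], "formula")
  db <- build_set_database(sets, min_set_size = 1)
  res <- run_mplage(ds$matrix, db, ds$annotations, c("case", "control"),
                    n_perm = 150, seed = 6)
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$set_id, c("ghost", "lonely"))
  expect_equal(skipped$reason[skipped$set_id == "ghost"], "no_mapped_features")
  expect_equal(skipped$reason[skipped$set_id == "lonely"], "too_few_features")
  # a constant-AL set cannot be scored: p = 1
  vals <- ds$matrix$values
  vals[1:2, ] <- 1
  m2 <- intensity_matrix(vals, ds$matrix$design)
  res2 <- run_mplage(m2, db, ds$annotations, c("case", "control"),
                     n_perm = 150, seed = 6)
  expect_equal(res2$p_value[res2$set_id == "Two"], 1)
})
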