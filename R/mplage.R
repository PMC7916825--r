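#' Per-sample activity levels of a metabolite set
#'
#' Decomposes a set's feature-intensity submatrix X (features x samples) by
#' singular value decomposition X = U D V' and returns the first row of V':
#' the unit-norm vector of coefficients with which the leading "metacompound"
#' (first left singular vector, the direction capturing the largest share of
#' variance) expresses itself in each sample. Coordinated intensity changes
#' across the set's features — increases, decreases, or both at once — show
#' up as between-group structure in these activity-level (AL) scores.
#'
#' The singular vector's sign is arbitrary; for determinism it is fixed so
#' that the entry of largest absolute value is positive. All downstream
#' p-values are invariant under this choice.
#'
#' @param X Numeric matrix (features x samples) or an [intensity_matrix()].
#' @return Numeric vector of AL scores, one per sample (unit Euclidean norm).
#' @export
activity_levels <- function(X) {
  if (inherits(X, "intensity_matrix")) X <- X$values
  X <- as.matrix(X)
  if (nrow(X) < 1 || ncol(X) < 2) stop("set matrix needs >= 1 feature and >= 2 samples")
  if (nrow(X) == 1) {
    v <- as.numeric(X[1, ])
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) return(setNames(rep(0, length(v)), colnames(X)))
    v <- v / nrm
  } else {
    v <- svd(X, nu = 0, nv = 1)$v[, 1]
  }
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  setNames(v, colnames(X))
}

# Large finite stand-in for a t-statistic with zero standard error but a
# non-zero mean difference.
T_SENTINEL <- 1e6

#' Two-sample t-statistic on activity-level scores
#'
#' Welch (unequal-variance) two-sample t-statistic of case versus control AL
#' scores; `var_equal = TRUE` switches to the pooled-variance flavour. A zero
#' standard error with a non-zero mean difference is guarded to a large
#' finite sentinel (+/- 1e6); identical groups give 0.
#'
#' @param al Numeric vector of AL scores named by sample.
#' @param design Named character vector sample -> group.
#' @param comparison Character vector `c(case, control)`.
#' @param var_equal Use pooled variance instead of Welch.
#' @return The t-statistic (positive when case mean exceeds control mean).
#' @export
set_t_statistic <- function(al, design, comparison, var_equal = FALSE) {
  x <- al[names(design)[design == comparison[1]]]
  y <- al[names(design)[design == comparison[2]]]
  if (length(x) < 2 || length(y) < 2) stop("each comparison group needs >= 2 samples")
  welch_t(x, y, var_equal = var_equal)
}

welch_t <- function(x, y, var_equal = FALSE) {
  d <- mean(x) - mean(y)
  if (var_equal) {
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  } else {
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
  }
  if (!is.finite(se) || se == 0) {
    if (d == 0) return(0)
    return(sign(d) * T_SENTINEL)
  }
  d / se
}

# Vectorised Welch/pooled t for every row of `mat`, case columns vs control
# columns. Zero-SE rows map to the sentinel (or 0 when means also tie).
row_t_statistics <- function(mat, case_idx, ctrl_idx, var_equal = FALSE) {
  n1 <- length(case_idx); n2 <- length(ctrl_idx)
  x <- mat[, case_idx, drop = FALSE]; y <- mat[, ctrl_idx, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
  } else {
    se2 <- v1 / n1 + v2 / n2
  }
  d <- m1 - m2
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * T_SENTINEL))
  df <- if (var_equal) rep(n1 + n2 - 2, length(t)) else {
    ifelse(se2 > 0, se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))), 1)
  }
  list(t = t, df = df, se2 = se2)
}

#' Permutation null of set t-statistics
#'
#' Shuffles the sample labels of the comparison and recomputes the AL
#' t-statistic of every set in each round. With the default global scope the
#' minimum and maximum t across all sets are recorded per round; these
#' per-round extremes are the data to which the GEV tails are fitted. The
#' full sets-by-permutations t matrix is kept as well (used by the per-set
#' calibration option).
#'
#' @param als Matrix of AL scores, sets in rows, comparison samples in
#'   columns (column names are sample ids).
#' @param design Named character vector sample -> group.
#' @param comparison `c(case, control)`.
#' @param n_perm Number of permutation rounds (>= 100 for a stable GEV fit).
#' @param seed RNG seed (mandatory; recorded in the result).
#' @param var_equal Pooled-variance t instead of Welch.
#' @return Object of class `permutation_null`: list with `min_t`, `max_t`
#'   (length `n_perm`), `t_perm` (sets x n_perm), `n_perm`, `seed`.
#' @export
permutation_null <- function(als, design, comparison, n_perm = 1000, seed,
                             var_equal = FALSE) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for the permutation null")
  if (n_perm < 100) stop("n_perm must be >= 100 for a stable extreme-value fit")
  # canonical sample order: results do not depend on input column order
  samples <- sort(names(design)[design %in% comparison])
  als <- als[, samples, drop = FALSE]
  n <- length(samples)
  n1 <- sum(design[samples] == comparison[1])
  if (lfactorial(n) < log(n_perm)) {
    warning("fewer distinct label permutations than n_perm; sampling with replacement")
  }
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  # indicator of case membership after permutation: the first n1 labels are
  # case, so column j of the shuffled label vector is case when its shuffled
  # position is <= n1
  case_ind <- matrix(0, n, n_perm)
  case_ind[perms <= n1] <- 1
  t_perm <- block_t_statistics(als, case_ind, n1, n - n1, var_equal)
  structure(list(min_t = apply(t_perm, 2, min),
                 max_t = apply(t_perm, 2, max),
                 t_perm = t_perm, n_perm = n_perm, seed = seed),
            class = "permutation_null")
}

# t-statistics of every row of `als` under every case-assignment column of
# `case_ind` (samples x n_perm 0/1 matrix), via matrix products.
block_t_statistics <- function(als, case_ind, n1, n2, var_equal = FALSE) {
  ctrl_ind <- 1 - case_ind
  s1 <- als %*% case_ind;  s2 <- als %*% ctrl_ind
  q1 <- (als^2) %*% case_ind; q2 <- (als^2) %*% ctrl_ind
  m1 <- s1 / n1; m2 <- s2 / n2
  v1 <- pmax(q1 - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax(q2 - n2 * m2^2, 0) / (n2 - 1)
  if (var_equal) {
    se2 <- (((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)) * (1 / n1 + 1 / n2)
  } else {
    se2 <- v1 / n1 + v2 / n2
  }
  d <- m1 - m2
  t <- d / sqrt(se2)
  zero <- !is.finite(t)
  if (any(zero)) t[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * T_SENTINEL)
  t
}

#' GEV-calibrated two-sided p-value for an observed set t-statistic
#'
#' Evaluates the observed t against the two fitted extreme-value tails: the
#' upper-tail survival of the GEV fitted to per-round maxima, and the
#' lower-tail probability from the GEV fitted to negated per-round minima.
#' The two-sided p-value is `min(1, 2 * min(upper, lower))`. Because the
#' fitted tail is analytic, p-values below the raw permutation resolution
#' `1/(n_perm + 1)` are meaningful and are not floored by default; set
#' `floor_p = TRUE` to clip at the permutation resolution instead.
#'
#' @param t_obs Observed t-statistic(s).
#' @param gev_max [fit_gev()] result on the per-round maxima.
#' @param gev_min [fit_gev()] result on the negated per-round minima.
#' @param n_perm Number of permutation rounds (sets the optional floor).
#' @param floor_p Clip p-values below `1/(n_perm + 1)` up to that floor.
#' @return p-value(s) in (0, 1].
#' @export
calibrated_p_value <- function(t_obs, gev_max, gev_min, n_perm = 1000,
                               floor_p = FALSE) {
  upper <- pgev(t_obs, gev_max$loc, gev_max$scale, gev_max$shape, lower.tail = FALSE)
  lower <- pgev(-t_obs, gev_min$loc, gev_min$scale, gev_min$shape, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(upper, lower))
  lo <- if (floor_p) 1 / (n_perm + 1) else .Machine$double.eps
  pmin(pmax(p, lo), 1)
}

# Empirical analogue of calibrated_p_value built directly from the recorded
# per-round extremes (fallback when the GEV fit fails, and the cross-check
# route in tests).
empirical_extreme_p <- function(t_obs, max_t, min_t) {
  np <- length(max_t)
  upper <- (1 + vapply(t_obs, function(t) sum(max_t >= t), numeric(1))) / (np + 1)
  lower <- (1 + vapply(t_obs, function(t) sum(min_t <= t), numeric(1))) / (np + 1)
  pmin(1, 2 * pmin(upper, lower))
}

#' Rank metabolite sets by activity-level change (mPLAGE)
#'
#' The full pipeline for one two-group comparison: map each set to its
#' features, decompose each set's submatrix into per-sample activity levels,
#' compute the case-vs-control Welch t-statistic of the AL scores, build a
#' sample-label permutation null jointly over all sets, fit GEV distributions
#' to the per-round extreme t-statistics, and convert each observed t into a
#' calibrated two-sided p-value. Sets are returned ranked by p-value.
#'
#' @param m Preprocessed [intensity_matrix()].
#' @param db `set_database` of metabolite sets.
#' @param annotations Annotation data frame (adduct-filtered); may be `NULL`
#'   when every set is feature-keyed.
#' @param comparison `c(case, control)` factor-group labels.
#' @param n_perm Permutation rounds, default 1000.
#' @param seed RNG seed (mandatory).
#' @param min_set_size Minimum number of mapped features for a set to be
#'   scored; smaller sets are skipped and reported.
#' @param scope `"global"` (default): per-round extremes taken across all
#'   sets jointly, giving family-wise calibrated p-values as in maxT-style
#'   permutation testing. `"per_set"`: each set's p-value is its empirical
#'   two-sided permutation p from its own null t's (per-set calibrated,
#'   approximately uniform under the null).
#' @param p_method `"gev"` (default) or `"empirical"` for the global scope.
#' @param var_equal Pooled-variance t instead of Welch.
#' @param floor_p See [calibrated_p_value()].
#' @return data.frame with columns `set_id`, `name`, `n_features`,
#'   `coverage`, `t_statistic`, `p_value`, `rank`, sorted by ascending
#'   p-value (ties broken by set_id). Attributes: `skipped` (data.frame of
#'   set_id + reason), `gev_max`, `gev_min`, `null` (the
#'   [permutation_null()]), `comparison`, `seed`.
#' @export
run_mplage <- function(m, db, annotations = NULL, comparison, n_perm = 1000,
                       seed, min_set_size = 2,
                       scope = c("global", "per_set"),
                       p_method = c("gev", "empirical"),
                       var_equal = FALSE, floor_p = FALSE) {
  scope <- match.arg(scope)
  p_method <- match.arg(p_method)
  stopifnot(inherits(m, "intensity_matrix"), inherits(db, "set_database"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  check_two_group_design(m, comparison)
  if (is.null(annotations)) {
    annotations <- data.frame(feature_id = character(0), formula = character(0),
                              adduct = character(0))
  }
  mapping <- map_database(db, annotations, m)

  skipped <- data.frame(set_id = character(0), reason = character(0))
  scoreable <- character(0)
  al_list <- list()
  for (sid in names(db$sets)) {
    ids <- mapping$features[[sid]]
    if (length(ids) == 0) {
      skipped <- rbind(skipped, data.frame(set_id = sid, reason = "no_mapped_features"))
    } else if (length(ids) < min_set_size) {
      skipped <- rbind(skipped, data.frame(set_id = sid, reason = "too_few_features"))
    } else {
      scoreable <- c(scoreable, sid)
      al_list[[sid]] <- activity_levels(m$values[ids, , drop = FALSE])
    }
  }
  if (length(scoreable) == 0) stop("no scoreable sets: every set skipped")

  als <- do.call(rbind, al_list)
  design <- groups_of(m)
  case_idx <- which(design == comparison[1])
  ctrl_idx <- which(design == comparison[2])
  t_obs <- row_t_statistics(als, case_idx, ctrl_idx, var_equal = var_equal)$t
  # sets whose AL scores are constant across the comparison have no defined t
  flat <- apply(als[, c(case_idx, ctrl_idx), drop = FALSE], 1, function(v) var(v) == 0)

  null <- permutation_null(als, design, comparison, n_perm = n_perm, seed = seed,
                           var_equal = var_equal)
  gev_max <- gev_min <- NULL
  if (scope == "global") {
    if (p_method == "gev") {
      gev_max <- fit_gev(null$max_t)
      gev_min <- fit_gev(-null$min_t)
      if (gev_max$converged && gev_min$converged) {
        p <- calibrated_p_value(t_obs, gev_max, gev_min, n_perm = n_perm,
                                floor_p = floor_p)
      } else {
        warning("GEV fit did not converge; falling back to empirical extreme p-values")
        p <- empirical_extreme_p(t_obs, null$max_t, null$min_t)
      }
    } else {
      p <- empirical_extreme_p(t_obs, null$max_t, null$min_t)
    }
  } else {
    np <- null$n_perm
    p <- vapply(seq_along(t_obs), function(i) {
      tp <- null$t_perm[i, ]
      min(1, 2 * min((1 + sum(tp >= t_obs[i])) / (np + 1),
                     (1 + sum(tp <= t_obs[i])) / (np + 1)))
    }, numeric(1))
  }
  p[flat] <- 1

  res <- data.frame(
    set_id = scoreable,
    name = vapply(db$sets[scoreable], function(s) s$name, character(1)),
    n_features = vapply(mapping$features[scoreable], length, integer(1)),
    coverage = as.numeric(mapping$coverage[scoreable]),
    t_statistic = as.numeric(t_obs),
    p_value = as.numeric(p),
    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "gev_max") <- gev_max
  attr(res, "gev_min") <- gev_min
  attr(res, "null") <- null
  attr(res, "comparison") <- comparison
  attr(res, "seed") <- seed
  attr(res, "method") <- "mplage"
  res
}
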