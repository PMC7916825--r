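# Signal-to-noise ranking metric for every row of `mat`, case vs control,
# with the conventional low-variance guard: each group's sd is floored at
# 0.2 * |group mean| (0.2 when the mean is 0).
signal_to_noise <- function(mat, case_idx, ctrl_idx) {
  x <- mat[, case_idx, drop = FALSE]; y <- mat[, ctrl_idx, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  s1 <- sqrt(rowSums((x - m1)^2) / (length(case_idx) - 1))
  s2 <- sqrt(rowSums((y - m2)^2) / (length(ctrl_idx) - 1))
  s1 <- pmax(s1, 0.2 * pmax(abs(m1), 1))
  s2 <- pmax(s2, 0.2 * pmax(abs(m2), 1))
  (m1 - m2) / (s1 + s2)
}


#' Gene set enrichment analysis of metabolite sets
#'
#' The original weighted running-sum formulation applied to metabolite sets:
#' features are ranked by the signal-to-noise ratio between case and
#' control; each set's enrichment score (ES) is the largest signed deviation
#' of a running sum that gains `|metric|^weight / NR` at member features and
#' loses `1/(N - K)` at non-members. Significance comes from permuting the
#' sample labels, recomputing the ranking metric and ES each round, and
#' comparing the observed ES against the same-signed portion of its
#' permutation null. The normalised ES divides by the mean magnitude of the
#' same-signed null scores.
#'
#' @param m Preprocessed [intensity_matrix()].
#' @param db `set_database`.
#' @param annotations Annotation data frame, or `NULL` for feature-keyed
#'   sets.
#' @param comparison `c(case, control)`.
#' @param n_perm Sample-label permutations, default 1000 (>= 100).
#' @param seed RNG seed (mandatory).
#' @param weight Exponent on the ranking metric in the running sum,
#'   default 1.
#' @param min_set_size Minimum mapped features for a set to be scored.
#' @return data.frame with columns `set_id`, `name`, `n_features`,
#'   `coverage`, `es`, `nes`, `p_value`, `rank`, ranked by ascending
#'   p-value. Attribute `skipped` as in [run_mplage()].
#' @export
gsea <- function(m, db, annotations = NULL, comparison, n_perm = 1000, seed,
                 weight = 1, min_set_size = 2) {
  stopifnot(inherits(m, "intensity_matrix"), inherits(db, "set_database"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_perm < 100) stop("n_perm must be >= 100")
  check_two_group_design(m, comparison)
  if (is.null(annotations)) {
    annotations <- data.frame(feature_id = character(0), formula = character(0),
                              adduct = character(0))
  }
  mapping <- map_database(db, annotations, m)

  design <- groups_of(m)
  # canonical sample order: results do not depend on input column order
  samples <- sort(names(design)[design %in% comparison])
  vals <- m$values[, samples, drop = FALSE]
  n <- length(samples)
  case_here <- design[samples] == comparison[1]
  n1 <- sum(case_here); n2 <- n - n1

  skipped <- data.frame(set_id = character(0), reason = character(0))
  set_rows <- list()
  for (sid in names(db$sets)) {
    ids <- mapping$features[[sid]]
    if (length(ids) == 0) {
      skipped <- rbind(skipped, data.frame(set_id = sid, reason = "no_mapped_features"))
    } else if (length(ids) < min_set_size) {
      skipped <- rbind(skipped, data.frame(set_id = sid, reason = "too_few_features"))
    } else if (length(ids) >= nrow(vals)) {
      stop("set '", sid, "' spans the entire ranked feature list")
    } else {
      set_rows[[sid]] <- match(ids, rownames(vals)) - 1L
    }
  }
  if (length(set_rows) == 0) stop("no scoreable sets: every set skipped")

  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  case_ind <- matrix(0, n, n_perm)
  case_ind[perms <= n1] <- 1
  metric <- s2n_metric_matrix(vals, cbind(as.numeric(case_here), case_ind))
  es_all <- gsea_es_matrix(metric, unname(set_rows), weight)
  es_obs <- es_all[, 1]
  es_null <- es_all[, -1, drop = FALSE]

  p <- nes <- numeric(length(es_obs))
  for (i in seq_along(es_obs)) {
    null_i <- es_null[i, ]
    if (es_obs[i] >= 0) {
      same <- null_i[null_i >= 0]
      p[i] <- (1 + sum(same >= es_obs[i])) / (1 + length(same))
    } else {
      same <- null_i[null_i < 0]
      p[i] <- (1 + sum(same <= es_obs[i])) / (1 + length(same))
    }
    denom <- mean(abs(same))
    nes[i] <- if (length(same) == 0 || denom == 0) NA_real_ else es_obs[i] / denom
  }

  sids <- names(set_rows)
  res <- data.frame(set_id = sids,
                    name = vapply(db$sets[sids], function(s) s$name, character(1)),
                    n_features = vapply(set_rows, length, integer(1)),
                    coverage = as.numeric(mapping$coverage[sids]),
                    es = es_obs, nes = nes, p_value = p,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "comparison") <- comparison
  attr(res, "seed") <- seed
  attr(res, "method") <- "gsea"
  res
}
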