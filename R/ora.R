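#' Per-feature differential-intensity calls
#'
#' Two-sample Welch t-test on every feature's preprocessed intensities, case
#' versus control; a feature is called differentially expressed (DE) when its
#' two-sided p-value falls below `alpha_feature`. Zero-variance features get
#' p = 1. This is the feature-selection step that overrepresentation
#' analysis requires.
#'
#' @param m Preprocessed [intensity_matrix()].
#' @param comparison `c(case, control)` group labels.
#' @param alpha_feature Per-feature significance threshold, default 0.05.
#' @param var_equal Pooled-variance t instead of Welch.
#' @return data.frame with columns `feature_id`, `t_statistic`, `p_value`,
#'   `de` (logical).
#' @export
feature_significance <- function(m, comparison, alpha_feature = 0.05,
                                 var_equal = FALSE) {
  stopifnot(inherits(m, "intensity_matrix"))
  check_two_group_design(m, comparison)
  design <- groups_of(m)
  res <- row_t_statistics(m$values,
                          which(design == comparison[1]),
                          which(design == comparison[2]),
                          var_equal = var_equal)
  p <- ifelse(res$se2 > 0, 2 * pt(-abs(res$t), df = res$df), 1)
  data.frame(feature_id = rownames(m$values),
             t_statistic = as.numeric(res$t),
             p_value = as.numeric(p),
             de = as.numeric(p) < alpha_feature,
             stringsAsFactors = FALSE)
}

#' Overrepresentation analysis of metabolite sets
#'
#' Classic ORA: features are first called DE by a per-feature t-test
#' ([feature_significance()]); each set is then tested for containing more
#' DE features than expected under random draws from the background, with a
#' one-sided (upper-tail) hypergeometric test — equivalently Fisher's exact
#' upper tail. For a background of N features of which n are DE, a set
#' covering K background features with k of them DE gets
#' p = P(X >= k), X ~ Hypergeometric(N, n, K).
#'
#' @param m Preprocessed [intensity_matrix()].
#' @param db `set_database`.
#' @param annotations Annotation data frame (adduct-filtered), or `NULL` for
#'   feature-keyed sets.
#' @param comparison `c(case, control)`.
#' @param alpha_feature Per-feature DE threshold, default 0.05.
#' @param background `"mapped"` (default): all features mapped to at least
#'   one set; `"all"`: every feature in the matrix.
#' @param min_set_size Minimum mapped features for a set to be scored.
#' @param var_equal Pooled-variance feature t-tests.
#' @return data.frame with columns `set_id`, `name`, `n_features` (K),
#'   `coverage`, `k_de`, `n_de_background`, `n_background`, `p_value`,
#'   `rank`, ranked by ascending p-value. Attribute `skipped` as in
#'   [run_mplage()].
#' @export
ora <- function(m, db, annotations = NULL, comparison, alpha_feature = 0.05,
                background = c("mapped", "all"), min_set_size = 2,
                var_equal = FALSE) {
  background <- match.arg(background)
  stopifnot(inherits(m, "intensity_matrix"), inherits(db, "set_database"))
  if (is.null(annotations)) {
    annotations <- data.frame(feature_id = character(0), formula = character(0),
                              adduct = character(0))
  }
  mapping <- map_database(db, annotations, m)
  bg <- if (background == "all") rownames(m$values) else {
    unique(unlist(mapping$features, use.names = FALSE))
  }
  if (length(bg) == 0) stop("empty background: no features map to any set")

  de_tab <- feature_significance(m, comparison, alpha_feature = alpha_feature,
                                 var_equal = var_equal)
  de_ids <- de_tab$feature_id[de_tab$de]
  N <- length(bg)
  n_de <- sum(de_ids %in% bg)

  skipped <- data.frame(set_id = character(0), reason = character(0))
  rows <- list()
  for (sid in names(db$sets)) {
    ids <- intersect(mapping$features[[sid]], bg)
    if (length(ids) == 0) {
      skipped <- rbind(skipped, data.frame(set_id = sid, reason = "no_mapped_features"))
      next
    }
    if (length(ids) < min_set_size) {
      skipped <- rbind(skipped, data.frame(set_id = sid, reason = "too_few_features"))
      next
    }
    K <- length(ids)
    k <- sum(ids %in% de_ids)
    p <- phyper(k - 1, n_de, N - n_de, K, lower.tail = FALSE)
    rows[[sid]] <- data.frame(set_id = sid, name = db$sets[[sid]]$name,
                              n_features = K,
                              coverage = as.numeric(mapping$coverage[sid]),
                              k_de = k, n_de_background = n_de, n_background = N,
                              p_value = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no scoreable sets: every set skipped")
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "comparison") <- comparison
  attr(res, "method") <- "ora"
  res
}
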