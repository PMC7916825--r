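#' Perturbation grids for the synthetic benchmark
#'
#' `decoy_grid()` covers increasing decoy-feature severity at no
#' missingness; `missing_grid()` varies the feature-removal probability at a
#' fixed decoy level of 100% (equal numbers of changing and non-changing
#' features), the protocol used for the missing-features experiment.
#'
#' @param levels Decoy levels (percent).
#' @param probs Missing-feature probabilities.
#' @param decoy_level Decoy level held fixed while missingness varies.
#' @return data.frame with columns `decoy_level`, `missing_prob`.
#' @export
decoy_grid <- function(levels = c(0, 25, 50, 100, 250, 500, 1000)) {
  data.frame(decoy_level = levels, missing_prob = 0)
}

#' @rdname decoy_grid
#' @export
missing_grid <- function(probs = c(0.2, 0.4, 0.6, 0.8), decoy_level = 100) {
  data.frame(decoy_level = decoy_level, missing_prob = probs)
}

#' Run the synthetic benchmark
#'
#' For every grid row and replicate: generate a fresh synthetic dataset,
#' apply the decoy and missing-feature perturbations, run every requested
#' ranking method on the byte-identical perturbed dataset, and score the
#' ranking against the truth at `alpha`. With `truth_mode = "planted"` the
#' truth is the set of planted changing pathways; with
#' `truth_mode = "full_data"` each method is first run on the unperturbed
#' dataset and its own significant sets (at `full_data_thresholds`) become
#' its truth — the protocol used to assess robustness against a complete
#' data set.
#'
#' @param methods Subset of `c("mplage", "ora", "gsea")`.
#' @param grid data.frame with columns `decoy_level`, `missing_prob` (see
#'   [decoy_grid()]).
#' @param n_reps Replicates per grid row.
#' @param base_seed Base RNG seed; every replicate seed derives from it.
#' @param n_perm Permutations for mPLAGE and GSEA.
#' @param alpha Significance threshold used to call positives, default 0.05.
#' @param alpha_feature Per-feature DE threshold for ORA.
#' @param effect_size,sigma,n_per_group Passed to
#'   [simulate_pathway_data()].
#' @param truth_mode `"planted"` (default) or `"full_data"`.
#' @param full_data_thresholds Per-method truth thresholds for
#'   `truth_mode = "full_data"`.
#' @param verbose Print a progress line per grid row.
#' @return Object of class `benchmark_result`: list with `metrics` (one row
#'   per method x grid row x replicate: TP/FP/FN, precision, recall, F1),
#'   `true_set_pvalues` (long table of per-true-set p-values), and `config`.
#' @export
run_benchmark <- function(methods = c("mplage", "ora", "gsea"),
                          grid = decoy_grid(),
                          n_reps = 100,
                          base_seed = 1,
                          n_perm = 1000,
                          alpha = 0.05,
                          alpha_feature = 0.05,
                          effect_size = 2.2,
                          sigma = 1,
                          n_per_group = 4,
                          truth_mode = c("planted", "full_data"),
                          full_data_thresholds = c(mplage = 0.05, ora = 0.05,
                                                   gsea = 0.25),
                          verbose = FALSE) {
  methods <- match.arg(methods, c("mplage", "ora", "gsea"), several.ok = TRUE)
  truth_mode <- match.arg(truth_mode)
  stopifnot(all(c("decoy_level", "missing_prob") %in% names(grid)), n_reps >= 1)

  metrics <- list()
  pvals <- list()
  row_i <- 0
  for (g in seq_len(nrow(grid))) {
    level <- grid$decoy_level[g]
    miss <- grid$missing_prob[g]
    if (verbose) {
      message(sprintf("benchmark: decoys %d%%, missing %d%%, %d replicates",
                      as.integer(level), as.integer(round(100 * miss)), n_reps))
    }
    for (r in seq_len(n_reps)) {
      rep_seed <- (base_seed + 7919L * ((g - 1L) * n_reps + r)) %% .Machine$integer.max
      ds <- simulate_pathway_data(rep_seed, n_per_group = n_per_group,
                                  effect_size = effect_size, sigma = sigma)
      truth <- setNames(rep(list(ds$truth), length(methods)), methods)
      if (truth_mode == "full_data") {
        full <- run_methods(ds, methods, n_perm, rep_seed, alpha_feature)
        truth <- truth_from_full_data(full, full_data_thresholds)
      }
      ds <- add_decoys(ds, level)
      if (miss > 0) ds <- drop_features(ds, miss)
      results <- run_methods(ds, methods, n_perm, rep_seed, alpha_feature)
      for (meth in methods) {
        pv <- result_pvalues(results[[meth]])
        counts <- classify_hits(pv, truth[[meth]], alpha)
        scores <- prf(counts["TP"], counts["FP"], counts["FN"])
        row_i <- row_i + 1
        metrics[[row_i]] <- data.frame(
          method = meth, decoy_level = level, missing_prob = miss,
          replicate = r, TP = counts[["TP"]], FP = counts[["FP"]],
          FN = counts[["FN"]], precision = scores[["precision"]],
          recall = scores[["recall"]], f1 = scores[["f1"]],
          stringsAsFactors = FALSE)
        true_present <- intersect(ds$truth, names(pv))
        if (length(true_present) > 0) {
          pvals[[row_i]] <- data.frame(
            method = meth, decoy_level = level, missing_prob = miss,
            replicate = r, set_id = true_present,
            p_value = unname(pv[true_present]), stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 true_set_pvalues = do.call(rbind, pvals),
                 config = list(methods = methods, grid = grid, n_reps = n_reps,
                               base_seed = base_seed, n_perm = n_perm,
                               alpha = alpha, alpha_feature = alpha_feature,
                               effect_size = effect_size, sigma = sigma,
                               n_per_group = n_per_group,
                               truth_mode = truth_mode)),
            class = "benchmark_result")
}

# All requested methods on one dataset; the methods share the same matrix,
# annotation table and set database objects by construction.
run_methods <- function(ds, methods, n_perm, seed, alpha_feature) {
  comparison <- c("case", "control")
  out <- list()
  for (meth in methods) {
    out[[meth]] <- switch(meth,
      mplage = run_mplage(ds$matrix, ds$sets, ds$annotations, comparison,
                          n_perm = n_perm, seed = seed),
      ora = ora(ds$matrix, ds$sets, ds$annotations, comparison,
                alpha_feature = alpha_feature),
      gsea = gsea(ds$matrix, ds$sets, ds$annotations, comparison,
                  n_perm = n_perm, seed = seed))
  }
  out
}

#' Summarise a benchmark run
#'
#' Aggregates per (method, decoy level, missing probability): the median and
#' mean p-value assigned to the true changing pathways (pooled over pathways
#' and replicates) and the mean and median F1 score.
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return data.frame of summary rows.
#' @export
summary.benchmark_result <- function(object, ...) {
  pv <- object$true_set_pvalues
  met <- object$metrics
  key <- function(d) interaction(d$method, d$decoy_level, d$missing_prob, drop = TRUE)
  agg <- lapply(split(pv, key(pv)), function(d) {
    data.frame(method = d$method[1], decoy_level = d$decoy_level[1],
               missing_prob = d$missing_prob[1],
               median_p = median(d$p_value), mean_p = mean(d$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  f1 <- lapply(split(met, key(met)), function(d) {
    data.frame(method = d$method[1], decoy_level = d$decoy_level[1],
               missing_prob = d$missing_prob[1],
               mean_f1 = mean(d$f1), median_f1 = median(d$f1),
               stringsAsFactors = FALSE)
  })
  f1 <- do.call(rbind, f1)
  out <- merge(out, f1, by = c("method", "decoy_level", "missing_prob"),
               all = TRUE)
  out <- out[order(out$decoy_level, out$missing_prob, out$method), ]
  rownames(out) <- NULL
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("benchmark_result: %s; %d grid rows x %d replicates\n",
              paste(cfg$methods, collapse = "/"), nrow(cfg$grid), cfg$n_reps))
  print(summary(x))
  invisible(x)
}

#' Boxplots of true-pathway p-values or F1 scores across perturbation levels
#'
#' @param x A `benchmark_result`.
#' @param what `"p_value"` (true-pathway p-values, log10 axis) or `"f1"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.benchmark_result <- function(x, what = c("p_value", "f1"), ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the ggplot2 package")
  }
  what <- match.arg(what)
  varying <- if (length(unique(x$config$grid$missing_prob)) > 1) "missing_prob" else "decoy_level"
  if (what == "p_value") {
    d <- x$true_set_pvalues
    d$level <- factor(d[[varying]])
    ggplot2::ggplot(d, ggplot2::aes(x = level, y = p_value, fill = method)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::scale_y_log10() +
      ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed", colour = "red") +
      ggplot2::labs(x = varying, y = "true-pathway p-value")
  } else {
    d <- x$metrics
    d$level <- factor(d[[varying]])
    ggplot2::ggplot(d, ggplot2::aes(x = level, y = f1, fill = method)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::labs(x = varying, y = "F1 score")
  }
}
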