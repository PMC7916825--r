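#' Classify a ranked result against known truth
#'
#' Sets with p-value strictly below `alpha` are called positive; positives in
#' the truth are true positives, positives outside it false positives, and
#' truth members not called positive (including sets absent from the ranking,
#' e.g. skipped as unscoreable) are false negatives.
#'
#' @param pvalues Named numeric vector, set_id -> p-value.
#' @param truth Character vector of truly changing set ids.
#' @param alpha Significance threshold, default 0.05.
#' @return Named integer vector `c(TP, FP, FN)`.
#' @export
classify_hits <- function(pvalues, truth, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  positives <- names(pvalues)[pvalues < alpha]
  c(TP = length(intersect(positives, truth)),
    FP = length(setdiff(positives, truth)),
    FN = length(setdiff(truth, positives)))
}

#' Precision, recall and F1 from classification counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean.
#' Undefined ratios (zero denominators) are reported as 0, the conservative
#' convention.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Per-method truth from full-data results
#'
#' The robustness-to-missing-features protocol takes each method's
#' significant sets on the complete (unperturbed) data as that method's own
#' ground truth, then measures how well the method recovers this truth from
#' degraded data. Thresholds are method-specific: 0.05 conventionally, with
#' a more permissive 0.25 for GSEA.
#'
#' @param full_results Named list, method -> named p-value vector (or a
#'   ranked result data.frame with `set_id` and `p_value` columns) from the
#'   complete data.
#' @param thresholds Named numeric vector of per-method significance
#'   thresholds.
#' @return Named list, method -> character vector of truth set ids.
#' @export
truth_from_full_data <- function(full_results,
                                 thresholds = c(mplage = 0.05, ora = 0.05,
                                                gsea = 0.25)) {
  out <- list()
  for (meth in names(full_results)) {
    res <- full_results[[meth]]
    if (is.data.frame(res)) res <- setNames(res$p_value, res$set_id)
    if (!(meth %in% names(thresholds))) {
      stop("no threshold for method '", meth, "'")
    }
    thr <- thresholds[[meth]]
    out[[meth]] <- names(res)[res < thr]
  }
  out
}

result_pvalues <- function(res) setNames(res$p_value, res$set_id)
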