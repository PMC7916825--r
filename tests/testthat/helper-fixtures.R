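# Shared fixture builders and small oracles, all generated in code.

pv <- function(res) setNames(res$p_value, res$set_id)

# Raw-count style matrix with zeros (missing), 2 groups x 3 samples.
make_raw_matrix <- function() {
  vals <- rbind(
    F1 = c(0, 0, 0, 1000, 2000, 3000),
    F2 = c(0, 10, 20, 5, 5, 5),
    F3 = c(3, 4, 5, 6, 7, 8),
    F4 = c(100, 200, 400, 0, 0, 0))
  colnames(vals) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  intensity_matrix(vals, c(a1 = "case", a2 = "case", a3 = "case",
                           b1 = "control", b2 = "control", b3 = "control"))
}

# Deterministic toy for exact ORA counts: N = 20 features (all mapped), one
# focal set with K = 5 of which k = 4 are DE, n = 8 DE in total. DE features
# have a huge group shift with tiny within-group spread; non-DE features are
# constant (p = 1 by the zero-variance rule).
make_ora_toy <- function() {
  n_feat <- 20
  de <- c(1:4, 6:9)  # 8 DE features; 4 of them in the focal set (1:5)
  vals <- matrix(5, n_feat, 8)
  set.seed(421)
  vals[de, 1:4] <- 50 + matrix(rnorm(length(de) * 4, 0, 0.01), length(de))
  vals[de, 5:8] <- 5 + matrix(rnorm(length(de) * 4, 0, 0.01), length(de))
  rownames(vals) <- sprintf("F%02d", 1:n_feat)
  colnames(vals) <- c(paste0("c", 1:4), paste0("k", 1:4))
  design <- setNames(rep(c("case", "control"), each = 4), colnames(vals))
  m <- intensity_matrix(vals, design)
  ann <- data.frame(feature_id = rownames(vals),
                    formula = sprintf("FORM%02d", 1:n_feat),
                    adduct = "M+H", stringsAsFactors = FALSE)
  db <- build_set_database(list(
    metabolite_set("focal", "focal", ann$formula[1:5], "formula"),
    metabolite_set("rest", "rest", ann$formula[6:20], "formula")),
    min_set_size = 1)
  list(m = m, ann = ann, db = db, N = 20, K = 5, n = 8, k = 4)
}

# Upper-tail hypergeometric by exhaustive enumeration of the tail terms.
hyper_upper_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Running-sum enrichment score by explicit stepping through the ranked list.
es_oracle <- function(metric, members, weight = 1) {
  ord <- order(metric, decreasing = TRUE)
  hit <- ord %in% members
  w <- abs(metric[ord])^weight * hit
  nr <- sum(w)
  if (nr == 0) { w <- as.numeric(hit); nr <- sum(w) }
  running <- cumsum(w / nr - (!hit) / (length(metric) - length(members)))
  running[which.max(abs(running))]
}

# Bootstrap standard error of the log10 median of a p-value sample.
boot_se_log_median <- function(x, B = 200) {
  stats <- replicate(B, log10(median(sample(x, replace = TRUE))))
  sd(stats)
}

# Write a small CLI fixture (intensity with missing values, annotations with
# a to-be-filtered adduct, three sets, design) into `dir`.
write_cli_fixture <- function(dir) {
  set.seed(77)
  n_feat <- 30
  vals <- matrix(round(exp(rnorm(n_feat * 8, 11, 0.4))), n_feat, 8)
  vals[1:10, 1:4] <- round(vals[1:10, 1:4] * 8)  # changing block
  vals[sample(length(vals), 15)] <- 0            # missing values
  feature_ids <- sprintf("peak%03d", 1:n_feat)
  samples <- c(paste0("case_", 1:4), paste0("ctrl_", 1:4))
  dimnames(vals) <- list(feature_ids, samples)

  intensity_path <- file.path(dir, "intensity.csv")
  write.csv(data.frame(feature_id = feature_ids, vals, check.names = FALSE),
            intensity_path, row.names = FALSE, quote = FALSE)

  ann <- data.frame(feature_id = c(feature_ids, "peak001"),
                    formula = c(sprintf("C%dH%dO2", 5 + 1:n_feat, 8 + 1:n_feat),
                                "NaCl"),
                    adduct = c(rep(c("M+H", "M-H"), length.out = n_feat), "M+Na"))
  ann_path <- file.path(dir, "annotations.csv")
  write.csv(ann, ann_path, row.names = FALSE, quote = FALSE)

  members <- list(setA = ann$formula[1:10], setB = ann$formula[11:22],
                  setC = ann$formula[23:30])
  sets <- do.call(rbind, lapply(names(members), function(s) {
    data.frame(set_id = s, set_name = paste0("Set ", s), member = members[[s]],
               member_kind = "formula")
  }))
  sets_path <- file.path(dir, "sets.csv")
  write.csv(sets, sets_path, row.names = FALSE, quote = FALSE)

  design_path <- file.path(dir, "design.txt")
  writeLines(c("# synthetic CLI fixture",
               paste("case:", paste(samples[1:4], collapse = ", ")),
               paste("control:", paste(samples[5:8], collapse = ", "))),
             design_path)
  list(intensity = intensity_path, annotations = ann_path, sets = sets_path,
       design = design_path)
}
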