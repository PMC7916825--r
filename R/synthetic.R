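#' Simulate a two-condition metabolomics dataset with planted pathways
#'
#' Builds the synthetic benchmark dataset: seven "changing" pathways of
#' known sizes whose member features show a clear case/control block
#' structure, plus background pathways whose features do not change, over a
#' two-condition design with a handful of samples per group. Control
#' intensities are drawn N(0, sigma^2); changing-feature case intensities
#' are shifted by `effect_size * sigma`. Every feature row is standardised
#' (zero mean, unit variance across all samples) as input to the ranking
#' methods, mirroring how decoy/background features are standardised with
#' the rest. Each feature carries a unique formula annotation ((M+H)+
#' adduct), and pathways are formula-keyed, so the formula-mapping machinery
#' is exercised end to end.
#'
#' @param seed RNG seed (mandatory; everything is reproducible from it).
#' @param changing_sizes Sizes of the planted changing pathways, default
#'   `c(2, 4, 6, 10, 20, 40, 80)`; the pathways are named after their sizes
#'   (Two, Four, ..., Eighty) when the default sizes are used.
#' @param n_background Number of non-changing background pathways,
#'   default 100.
#' @param background_size_range Inclusive range of background pathway sizes,
#'   default `c(5, 50)` (drawn uniformly).
#' @param n_per_group Samples per condition, default 4.
#' @param effect_size Between-group mean shift of changing features in
#'   standard-deviation units. The default 2.2 is the generator's
#'   calibration: it produces a clearly visible case/control block structure
#'   while placing the benchmark's median true-pathway p-values for all
#'   three ranking methods in the regime reported for this class of
#'   comparison (see the methods vignette).
#' @param sigma Within-group standard deviation of raw intensities,
#'   default 1.
#' @return Object of class `synthetic_dataset`: list with `matrix`
#'   ([intensity_matrix()], standardised), `annotations`, `sets`
#'   (`set_database`), `truth` (ids of the changing pathways),
#'   `perturbations` (log of applied perturbations), `seed`.
#' @export
simulate_pathway_data <- function(seed,
                                  changing_sizes = c(2, 4, 6, 10, 20, 40, 80),
                                  n_background = 100,
                                  background_size_range = c(5, 50),
                                  n_per_group = 4,
                                  effect_size = 2.2,
                                  sigma = 1) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_per_group >= 2, effect_size >= 0, sigma > 0,
            length(changing_sizes) >= 1, all(changing_sizes >= 1))
  default_names <- c(`2` = "Two", `4` = "Four", `6` = "Six", `10` = "Ten",
                     `20` = "Twenty", `40` = "Forty", `80` = "Eighty")
  set_names <- default_names[as.character(changing_sizes)]
  set_names[is.na(set_names)] <- paste0("Changing_", changing_sizes[is.na(set_names)])

  with_seed(seed, {
    bg_sizes <- sample(seq(background_size_range[1], background_size_range[2]),
                       n_background, replace = TRUE)
    n_changing <- sum(changing_sizes)
    n_feat <- n_changing + sum(bg_sizes)
    n_samp <- 2 * n_per_group
    samples <- c(paste0("case_", seq_len(n_per_group)),
                 paste0("control_", seq_len(n_per_group)))
    design <- setNames(rep(c("case", "control"), each = n_per_group), samples)

    vals <- matrix(rnorm(n_feat * n_samp, 0, sigma), n_feat, n_samp)
    vals[seq_len(n_changing), seq_len(n_per_group)] <-
      vals[seq_len(n_changing), seq_len(n_per_group)] + effect_size * sigma
    feature_ids <- sprintf("F%05d", seq_len(n_feat))
    dimnames(vals) <- list(feature_ids, samples)
    vals <- standardise_rows(vals)

    formulae <- sprintf("CHM%05d", seq_len(n_feat))
    annotations <- data.frame(feature_id = feature_ids, formula = formulae,
                              adduct = "M+H", stringsAsFactors = FALSE)

    sets <- list()
    offset <- 0
    for (i in seq_along(changing_sizes)) {
      members <- formulae[offset + seq_len(changing_sizes[i])]
      sets[[set_names[i]]] <- metabolite_set(set_names[i], set_names[i],
                                             members, "formula", "pathway")
      offset <- offset + changing_sizes[i]
    }
    for (b in seq_len(n_background)) {
      sid <- sprintf("Background_%03d", b)
      members <- formulae[offset + seq_len(bg_sizes[b])]
      sets[[sid]] <- metabolite_set(sid, sid, members, "formula", "pathway")
      offset <- offset + bg_sizes[b]
    }
    db <- build_set_database(sets, source_tag = "synthetic", min_set_size = 1)

    structure(list(matrix = intensity_matrix(vals, design),
                   annotations = annotations,
                   sets = db,
                   truth = unname(set_names),
                   perturbations = list(),
                   seed = seed),
              class = "synthetic_dataset")
  })
}

# Row-wise standardisation to zero mean, unit (sample) variance.
standardise_rows <- function(vals) {
  ctr <- vals - rowMeans(vals)
  s <- sqrt(rowSums(ctr^2) / (ncol(vals) - 1))
  s[s == 0] <- 1
  ctr / s
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d features x %d samples, %d sets (%d changing)\n",
              nrow(x$matrix$values), ncol(x$matrix$values), length(x$sets$sets),
              length(x$truth)))
  if (length(x$perturbations) > 0) {
    cat("perturbations:",
        paste(vapply(x$perturbations, function(p) p$label, character(1)),
              collapse = "; "), "\n")
  }
  invisible(x)
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Add decoy features to the changing pathways
#'
#' Mimics mis-annotated or noisy set members: for each changing pathway,
#' `round(level/100 * original size)` new non-changing features (drawn from
#' the same normal distribution as the background, standardised with the
#' rest, identical across conditions in expectation) are appended to the
#' intensity matrix and added to that pathway's membership. Background
#' pathways are untouched. Counts are rounded half away from zero, so a
#' 25% level adds one decoy to a two-feature pathway.
#'
#' @param ds A `synthetic_dataset`.
#' @param level Decoy level as a percentage of each changing pathway's
#'   original size; the benchmark grid uses
#'   0, 25, 50, 100, 250, 500, 1000. Other non-negative values are accepted
#'   with a warning.
#' @param sigma Standard deviation of the raw decoy draws, default 1
#'   (matching the background features).
#' @param seed RNG seed; defaults to a value derived from the dataset's seed
#'   and the level, so the perturbation is reproducible without further
#'   bookkeeping.
#' @return The perturbed `synthetic_dataset`.
#' @export
add_decoys <- function(ds, level, sigma = 1, seed = NULL) {
  stopifnot(inherits(ds, "synthetic_dataset"), level >= 0)
  if (!(level %in% c(0, 25, 50, 100, 250, 500, 1000))) {
    warning("decoy level ", level, " is outside the standard benchmark grid")
  }
  if (level == 0) return(ds)
  if (is.null(seed)) seed <- (ds$seed + 104729L + as.integer(level)) %% .Machine$integer.max

  vals <- ds$matrix$values
  n_samp <- ncol(vals)
  counts <- vapply(ds$truth, function(sid) {
    as.integer(round_half_up(level / 100 * length(ds$sets$sets[[sid]]$members)))
  }, integer(1))
  total <- sum(counts)
  if (total == 0) return(ds)

  new_vals <- with_seed(seed, {
    standardise_rows(matrix(rnorm(total * n_samp, 0, sigma), total, n_samp))
  })
  new_ids <- sprintf("DECOY%05d_%d", seq_len(total), as.integer(level))
  new_formulae <- sprintf("DCHM%05d_%d", seq_len(total), as.integer(level))
  dimnames(new_vals) <- list(new_ids, colnames(vals))

  sets <- ds$sets$sets
  offset <- 0
  for (i in seq_along(ds$truth)) {
    sid <- ds$truth[i]
    if (counts[i] == 0) next
    add <- new_formulae[offset + seq_len(counts[i])]
    s <- sets[[sid]]
    sets[[sid]] <- metabolite_set(s$set_id, s$name, c(s$members, add),
                                  s$member_kind, s$source_tag)
    offset <- offset + counts[i]
  }

  ds$matrix <- intensity_matrix(rbind(vals, new_vals), ds$matrix$design)
  ds$annotations <- rbind(ds$annotations,
                          data.frame(feature_id = new_ids, formula = new_formulae,
                                     adduct = "M+H", stringsAsFactors = FALSE))
  ds$sets <- build_set_database(sets, source_tag = "synthetic", min_set_size = 1)
  ds$perturbations <- c(ds$perturbations,
                        list(list(label = sprintf("decoys_%d%%", as.integer(level)),
                                  type = "decoy", level = level,
                                  n_added = total, seed = seed)))
  ds
}

#' Randomly remove features from a synthetic dataset
#'
#' Each feature is independently removed with probability `p`, simulating
#' missing features in real peak data. Removal deletes the matrix row and
#' its annotation, so set memberships shrink through the formula mapping; a
#' pathway emptied (or reduced below the scoring minimum) by removal stays
#' in the database and is reported as unscoreable by the ranking methods.
#'
#' @param ds A `synthetic_dataset`.
#' @param p Removal probability in `[0, 1)`.
#' @param seed RNG seed; defaults to a value derived from the dataset's seed
#'   and `p`.
#' @return The perturbed `synthetic_dataset`.
#' @export
drop_features <- function(ds, p, seed = NULL) {
  stopifnot(inherits(ds, "synthetic_dataset"), p >= 0, p < 1)
  if (p == 0) return(ds)
  if (is.null(seed)) seed <- (ds$seed + 15485863L + as.integer(round(p * 1000))) %% .Machine$integer.max
  n_feat <- nrow(ds$matrix$values)
  keep <- with_seed(seed, runif(n_feat) >= p)
  if (!any(keep)) keep[1] <- TRUE  # never return an empty matrix
  kept_ids <- rownames(ds$matrix$values)[keep]
  ds$matrix <- intensity_matrix(ds$matrix$values[keep, , drop = FALSE],
                                ds$matrix$design)
  ds$annotations <- ds$annotations[ds$annotations$feature_id %in% kept_ids, ,
                                   drop = FALSE]
  ds$perturbations <- c(ds$perturbations,
                        list(list(label = sprintf("missing_%d%%", round(100 * p)),
                                  type = "missing", p = p,
                                  n_removed = sum(!keep), seed = seed)))
  ds
}
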