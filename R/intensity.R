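#' Construct a peak intensity matrix with an experimental design
#'
#' The central data container: a features-by-samples matrix of LC-MS peak
#' intensities together with the assignment of samples to factor groups.
#' Missing measurements are encoded as zero, the usual convention in exported
#' peak tables; [impute_missing()] replaces them before any statistics are
#' computed.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row
#'   names are feature identifiers, column names sample identifiers.
#' @param design Named character vector mapping each sample identifier to its
#'   factor-group label. Every column of `values` must appear exactly once.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` (the matrix) and `design` (named character vector, reordered to
#'   match the matrix columns).
#' @examples
#' x <- matrix(abs(rnorm(12, 1e5, 1e4)), 3, 4,
#'             dimnames = list(paste0("F", 1:3), paste0("S", 1:4)))
#' design <- c(S1 = "case", S2 = "case", S3 = "control", S4 = "control")
#' m <- intensity_matrix(x, design)
#' @export
intensity_matrix <- function(values, design) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("intensity values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("intensity matrix needs feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  design <- unlist(design)
  if (is.null(names(design))) stop("design must be a named vector: sample -> group")
  missing_samples <- setdiff(colnames(values), names(design))
  if (length(missing_samples) > 0) {
    stop("samples missing from design: ", paste(missing_samples, collapse = ", "))
  }
  design <- setNames(as.character(design[colnames(values)]), colnames(values))
  structure(list(values = values, design = design), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  grp <- table(groups_of(x))
  cat(sprintf("intensity_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

groups_of <- function(m) setNames(m$design, colnames(m$values))

# Column indices of a factor group; errors on unknown or empty groups.
group_cols <- function(m, group) {
  idx <- which(groups_of(m) == group)
  if (length(idx) == 0) stop("no samples in group '", group, "'")
  idx
}

check_two_group_design <- function(m, comparison) {
  if (length(comparison) != 2) stop("comparison must name (case, control) groups")
  for (g in comparison) {
    if (length(group_cols(m, g)) < 2) {
      stop("group '", g, "' has fewer than 2 samples; statistics need >= 2 per group")
    }
  }
  invisible(TRUE)
}

#' Impute missing peak intensities within factor groups
#'
#' Missing values (zeros) are filled per feature within each factor group:
#' when every sample of the group is missing the whole block is set to a
#' user-chosen minimum intensity, otherwise each missing sample is set to the
#' mean of the group's observed (non-zero) intensities. Observed values are
#' never altered, which makes the operation idempotent.
#'
#' @param m An [intensity_matrix()].
#' @param min_intensity Positive scalar used for all-missing blocks; roughly
#'   the instrument's detection floor. Default 5000 (arbitrary MS counts).
#' @return An `intensity_matrix` with no zero or missing entries.
#' @export
impute_missing <- function(m, min_intensity = 5000) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (!is.numeric(min_intensity) || length(min_intensity) != 1 || min_intensity <= 0) {
    stop("min_intensity must be a single positive number")
  }
  vals <- m$values
  vals[is.na(vals)] <- 0
  if (any(vals < 0)) stop("negative intensities are not valid input")
  groups <- groups_of(m)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    block <- vals[, idx, drop = FALSE]
    obs <- block > 0
    n_obs <- rowSums(obs)
    # rows with partial missingness: fill zeros with the mean of observed
    partial <- which(n_obs > 0 & n_obs < length(idx))
    if (length(partial) > 0) {
      means <- rowSums(block[partial, , drop = FALSE]) / n_obs[partial]
      for (k in seq_along(partial)) {
        r <- partial[k]
        block[r, !obs[r, ]] <- means[k]
      }
    }
    block[n_obs == 0, ] <- min_intensity
    vals[, idx] <- block
  }
  intensity_matrix(vals, m$design)
}

#' Log-transform and standardise a peak intensity matrix
#'
#' Optional normalisation ahead of activity decomposition: intensities are
#' taken to natural-log space and each feature row is centred and scaled to
#' zero mean and unit variance (sample variance, n - 1 denominator). By
#' default standardisation is applied within each factor group, which keeps
#' the groups comparable for the downstream between-group t-statistic; set
#' `scope = "row"` to standardise each feature across all samples instead.
#' A block with zero variance is centred only (no scaling) and a warning is
#' raised once.
#'
#' @param m A fully imputed [intensity_matrix()] (strictly positive values).
#' @param scope `"group"` (default) or `"row"`: the span over which each
#'   feature is centred and scaled.
#' @param log_transform Take natural logs first (default `TRUE`).
#' @return An `intensity_matrix` of normalised values (no longer raw counts).
#' @export
normalise_intensities <- function(m, scope = c("group", "row"), log_transform = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  scope <- match.arg(scope)
  vals <- m$values
  if (any(is.na(vals)) || any(vals <= 0)) {
    stop("normalisation requires strictly positive intensities; run impute_missing() first")
  }
  if (log_transform) vals <- log(vals)
  zero_var <- FALSE
  standardise_block <- function(block) {
    ctr <- block - rowMeans(block)
    s <- apply(block, 1, sd)
    flat <- !is.finite(s) | s == 0
    if (any(flat)) zero_var <<- TRUE
    s[flat] <- 1
    ctr / s
  }
  if (scope == "row") {
    vals <- standardise_block(vals)
  } else {
    groups <- groups_of(m)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) < 2) stop("group '", g, "' has < 2 samples; cannot standardise")
      vals[, idx] <- standardise_block(vals[, idx, drop = FALSE])
    }
  }
  if (zero_var) {
    warning("zero-variance feature block(s): centred without scaling")
  }
  intensity_matrix(vals, m$design)
}

#' Extract the intensity submatrix of one metabolite set
#'
#' Selects the rows of `m` whose annotated formula belongs to the set's
#' member formulae. All features sharing a member formula are included
#' (one formula frequently maps to several features), in the row order of
#' `m`.
#'
#' @param m An [intensity_matrix()].
#' @param annotations A data frame from [read_annotations()] (columns
#'   `feature_id`, `formula`, `adduct`), already restricted to allowed
#'   adducts.
#' @param member_formulae Character vector of the set's member formulae.
#' @return The row-submatrix as an `intensity_matrix`, or `NULL` when no
#'   feature maps to the set (the caller records the set as skipped).
#' @export
build_set_matrix <- function(m, annotations, member_formulae) {
  stopifnot(inherits(m, "intensity_matrix"))
  ids <- annotations$feature_id[annotations$formula %in% member_formulae]
  keep <- rownames(m$values) %in% ids
  if (!any(keep)) return(NULL)
  intensity_matrix(m$values[keep, , drop = FALSE], m$design)
}

#' Read a peak intensity table from delimited text
#'
#' Expects a header row of sample identifiers, a first column of feature
#' identifiers and numeric intensities elsewhere. Blank cells and `NA` are
#' coerced to zero (missing).
#'
#' @param path Path to the delimited file.
#' @param design Named character vector (sample -> group), e.g. from
#'   [read_design()].
#' @param sep Field delimiter, default comma.
#' @return An [intensity_matrix()].
#' @export
read_intensity_csv <- function(path, design, sep = ",") {
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("intensity table needs a feature column plus sample columns")
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[is.na(vals)] <- 0
  rownames(vals) <- ids
  intensity_matrix(vals, design)
}

# Accepted spellings of the two retained adducts; unicode minus normalised.
normalise_adduct <- function(x) {
  x <- gsub("−", "-", trimws(x))          # unicode minus
  x <- gsub("[()[:space:]]", "", x)            # decoration
  sub("[+-]+$", "", x)                         # trailing charge sign
}

#' Read a feature annotation table
#'
#' Columns `feature_id`, `formula`, `adduct` (a fourth ionisation-mode column
#' is tolerated and ignored). Only protonated (M+H)+ and deprotonated (M-H)-
#' records are retained: other adducts inflate false formula identifications
#' and are dropped, mirroring common practice for formula-level pathway
#' mapping. Formula strings are compared verbatim after whitespace stripping;
#' no chemical canonicalisation is attempted.
#'
#' @param path Path to the delimited file.
#' @param sep Field delimiter, default comma.
#' @param keep_adducts Adducts retained after normalisation.
#' @return data.frame with columns `feature_id`, `formula`, `adduct`.
#' @export
read_annotations <- function(path, sep = ",", keep_adducts = c("M+H", "M-H")) {
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("feature_id", "formula", "adduct")
  if (!all(need %in% names(tab))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  ann <- data.frame(feature_id = as.character(tab$feature_id),
                    formula = gsub("\\s", "", as.character(tab$formula)),
                    adduct = normalise_adduct(tab$adduct),
                    stringsAsFactors = FALSE)
  ann[ann$adduct %in% keep_adducts, , drop = FALSE]
}

#' Read an experimental design file
#'
#' Plain text, one line per group: `group_label: sample1, sample2, ...`.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the design file.
#' @return Named character vector sample -> group.
#' @export
read_design <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  design <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed design line: ", ln)
    group <- trimws(parts[1])
    samples <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    samples <- samples[nzchar(samples)]
    if (length(samples) == 0) stop("design group '", group, "' lists no samples")
    clash <- intersect(samples, names(design))
    if (length(clash) > 0) {
      stop("sample(s) assigned to more than one group: ", paste(clash, collapse = ", "))
    }
    design[samples] <- group
  }
  design
}
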