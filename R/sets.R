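#' Load metabolite-set definitions from a delimited file
#'
#' Metabolite sets are any user-defined grouping of LC-MS features: metabolic
#' pathways keyed by member compound formulae, or molecular families /
#' Mass2Motifs keyed directly by feature identifiers. The file is long-format
#' delimited text with columns `set_id`, `set_name`, `member`, `member_kind`
#' (`formula` or `feature`); one row per member. A set must be uniformly
#' formula-keyed or feature-keyed.
#'
#' @param path Path to the set definition file.
#' @param source_tag Provenance label (`"pathway"`, `"molecular_family"`,
#'   `"mass2motif"`, `"custom"`).
#' @param min_set_size Sets with fewer members are dropped on load (recorded
#'   in the metadata). Default 2: a single-member set has a degenerate
#'   rank-one decomposition. Molecular-family analyses conventionally use 10.
#' @param sep Field delimiter, default comma.
#' @return A `set_database`: list with `sets` (named list of
#'   `metabolite_set`), and `metadata` (source, min_set_size, counts).
#' @export
load_sets <- function(path, source_tag = "custom", min_set_size = 2, sep = ",") {
  if (min_set_size < 1) stop("min_set_size must be >= 1")
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"")
  need <- c("set_id", "set_name", "member", "member_kind")
  if (!all(need %in% names(tab))) {
    stop("set file needs columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!(tab$member_kind %in% c("formula", "feature")) |
                 !nzchar(trimws(tab$member)) | !nzchar(trimws(tab$set_id)))
  if (length(bad) > 0) {
    stop("malformed set rows (member_kind must be formula|feature, fields non-empty): lines ",
         paste(head(bad + 1L, 10), collapse = ", "))
  }
  sets <- list()
  for (sid in unique(tab$set_id)) {
    rows <- tab[tab$set_id == sid, , drop = FALSE]
    kind <- unique(rows$member_kind)
    if (length(kind) > 1) {
      stop("set '", sid, "' mixes formula and feature members")
    }
    nm <- unique(rows$set_name)
    if (length(nm) > 1) stop("set '", sid, "' has conflicting names")
    members <- unique(gsub("\\s", "", rows$member))
    sets[[sid]] <- metabolite_set(sid, nm, members, kind, source_tag)
  }
  build_set_database(sets, source_tag, min_set_size)
}

#' Construct a single metabolite set
#'
#' @param set_id Unique identifier.
#' @param name Display name.
#' @param members Character vector of member formulae or feature ids
#'   (duplicates removed).
#' @param member_kind `"formula"` or `"feature"`.
#' @param source_tag Provenance label.
#' @return An object of class `metabolite_set`.
#' @export
metabolite_set <- function(set_id, name, members, member_kind = c("formula", "feature"),
                           source_tag = "custom") {
  member_kind <- match.arg(member_kind)
  members <- unique(as.character(members))
  if (length(members) == 0) stop("set '", set_id, "' has no members")
  structure(list(set_id = as.character(set_id), name = as.character(name),
                 members = members, member_kind = member_kind,
                 source_tag = source_tag),
            class = "metabolite_set")
}

#' Assemble a set database from a list of metabolite sets
#'
#' @param sets List of [metabolite_set()] objects.
#' @param source_tag Provenance label stored in the metadata.
#' @param min_set_size Sets with fewer members are excluded (and counted).
#' @return A `set_database`, sets ordered by `set_id`.
#' @export
build_set_database <- function(sets, source_tag = "custom", min_set_size = 2) {
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate set_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(sets) <- ids
  sizes <- vapply(sets, function(s) length(s$members), integer(1))
  dropped <- sum(sizes < min_set_size)
  sets <- sets[sizes >= min_set_size]
  sets <- sets[order(names(sets))]
  structure(list(sets = sets,
                 metadata = list(source = source_tag,
                                 min_set_size = min_set_size,
                                 n_sets = length(sets),
                                 n_dropped_small = dropped)),
            class = "set_database")
}

#' @export
print.set_database <- function(x, ...) {
  cat(sprintf("set_database: %d sets (source: %s, min size %d, %d dropped as too small)\n",
              length(x$sets), x$metadata$source, x$metadata$min_set_size,
              x$metadata$n_dropped_small))
  invisible(x)
}

#' @export
length.set_database <- function(x) length(x$sets)

#' Map metabolite sets to intensity-matrix features
#'
#' Formula-keyed sets resolve through the annotation table: every feature
#' annotated with a member formula (restricted to the allowed adducts at
#' annotation load) is included, so one formula can contribute several
#' features. Feature-keyed sets resolve directly, intersected with the
#' features present in the matrix. Empty mappings are data, not errors.
#'
#' @param db A `set_database` from [load_sets()] / [build_set_database()].
#' @param annotations Annotation data frame ([read_annotations()]).
#' @param m An [intensity_matrix()].
#' @return Named list: `features` (set_id -> character vector of feature ids,
#'   in matrix row order), `coverage` (set_id -> fraction of members with at
#'   least one mapped feature), `unmapped` (ids of sets with no features).
#' @export
map_database <- function(db, annotations, m) {
  stopifnot(inherits(db, "set_database"), inherits(m, "intensity_matrix"))
  feat_order <- rownames(m$values)
  ann <- annotations[annotations$feature_id %in% feat_order, , drop = FALSE]
  by_formula <- split(ann$feature_id, ann$formula)
  features <- list()
  coverage <- numeric(0)
  for (sid in names(db$sets)) {
    s <- db$sets[[sid]]
    if (s$member_kind == "formula") {
      hits <- by_formula[intersect(s$members, names(by_formula))]
      ids <- unique(unlist(hits, use.names = FALSE))
      covered <- length(hits)
    } else {
      ids <- intersect(s$members, feat_order)
      covered <- length(ids)
    }
    ids <- feat_order[feat_order %in% ids]
    features[[sid]] <- ids
    coverage[sid] <- covered / length(s$members)
  }
  list(features = features,
       coverage = coverage,
       unmapped = names(features)[vapply(features, length, integer(1)) == 0])
}
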