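#' Load an NCBI-dialect taxonomy
#'
#' Parses `nodes.dmp` / `names.dmp` in the NCBI taxdump dialect: fields
#' separated by `"\t|\t"`, records terminated by `"\t|"`. Only the first three
#' fields of `nodes.dmp` (taxon id, parent id, rank) and the scientific-name
#' class of `names.dmp` are used. The result is verified acyclic with a single
#' root (a node that is its own parent) and every id must carry a scientific
#' name.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @param merged_path Optional path to `merged.dmp` (old id -> new id); when
#'   supplied, superseded ids are remapped transparently by [resolve_taxon()].
#' @return An object of class `taxonomy_db`.
#' @export
load_taxonomy <- function(nodes_path, names_path, merged_path = NULL) {
  nodes <- parse_dmp(nodes_path, min_fields = 3L)
  ids     <- as.integer(vapply(nodes, `[[`, character(1), 1L))
  parents <- as.integer(vapply(nodes, `[[`, character(1), 2L))
  ranks   <- vapply(nodes, `[[`, character(1), 3L)
  if (anyNA(ids) || anyNA(parents)) stop("nodes.dmp: non-integer taxon id")
  if (anyDuplicated(ids)) stop("nodes.dmp: duplicate taxon id")

  nm_rec <- parse_dmp(names_path, min_fields = 4L)
  nm_ids <- as.integer(vapply(nm_rec, `[[`, character(1), 1L))
  nm_txt <- vapply(nm_rec, `[[`, character(1), 2L)
  nm_cls <- vapply(nm_rec, `[[`, character(1), 4L)
  sci <- nm_cls == "scientific name"
  name_of <- nm_txt[sci][match(ids, nm_ids[sci])]
  if (anyNA(name_of)) {
    stop(sprintf("names.dmp: no scientific name for taxon id(s) %s",
                 paste(ids[is.na(name_of)], collapse = ", ")))
  }

  roots <- ids[ids == parents]
  if (length(roots) != 1L) {
    stop(sprintf("nodes.dmp: expected exactly one root (parent = self), found %d",
                 length(roots)))
  }
  if (!all(parents %in% ids)) stop("nodes.dmp: parent id not present in file")

  db <- structure(list(
    ids = ids, parent = parents, rank = ranks, name = name_of,
    root_id = roots, merged = NULL
  ), class = "taxonomy_db")

  check_acyclic(db)

  if (!is.null(merged_path)) {
    mg <- parse_dmp(merged_path, min_fields = 2L)
    old <- as.integer(vapply(mg, `[[`, character(1), 1L))
    new <- as.integer(vapply(mg, `[[`, character(1), 2L))
    if (!all(new %in% ids)) stop("merged.dmp: target id not in nodes.dmp")
    db$merged <- stats::setNames(new, old)
  }
  db
}

## Split taxdump records; errors carry the 1-based line number.
parse_dmp <- function(path, min_fields) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- sub("\t\\|$", "", lines[[i]])
    fields <- strsplit(rec, "\t|\t", fixed = TRUE)[[1L]]
    if (length(fields) < min_fields) {
      stop(sprintf("%s: malformed record at line %d (%d fields, expected >= %d)",
                   basename(path), i, length(fields), min_fields))
    }
    recs[[i]] <- fields
  }
  recs
}

check_acyclic <- function(db) {
  n <- length(db$ids)
  pos <- seq_len(n)
  parent_pos <- match(db$parent, db$ids)
  state <- integer(n)  # 0 unseen, 1 on current path, 2 done
  root_pos <- match(db$root_id, db$ids)
  state[root_pos] <- 2L
  for (start in pos) {
    path <- integer(0)
    i <- start
    while (state[i] == 0L) {
      state[i] <- 1L
      path <- c(path, i)
      i <- parent_pos[i]
    }
    if (state[i] == 1L) {
      stop(sprintf("nodes.dmp: cycle detected involving taxon id %d", db$ids[i]))
    }
    state[path] <- 2L
  }
  invisible(TRUE)
}

taxon_index <- function(db, id) {
  i <- match(id, db$ids)
  if (anyNA(i)) {
    stop(sprintf("unknown taxon id(s): %s", paste(id[is.na(i)], collapse = ", ")))
  }
  i
}

#' Resolve a taxon id, applying merged-id remapping
#'
#' @param db A `taxonomy_db`.
#' @param id Integer taxon ids.
#' @return Resolved ids; ids that are neither present nor remappable are
#'   returned as `NA`.
#' @export
resolve_taxon <- function(db, id) {
  id <- as.integer(id)
  out <- ifelse(id %in% db$ids, id, NA_integer_)
  if (!is.null(db$merged)) {
    miss <- is.na(out)
    out[miss] <- unname(db$merged[as.character(id[miss])])
  }
  out
}

#' Root-to-node lineage
#'
#' @param db A `taxonomy_db`.
#' @param id A single taxon id present in `db`.
#' @return Integer vector of taxon ids, root first, ending at `id`.
#' @export
lineage <- function(db, id) {
  i <- taxon_index(db, id)
  parent_pos <- match(db$parent, db$ids)
  root_pos <- match(db$root_id, db$ids)
  path <- i
  while (i != root_pos) {
    i <- parent_pos[i]
    path <- c(i, path)
  }
  db$ids[path]
}

#' Lowest common ancestor of a taxon set
#'
#' The deepest taxon lying on the root-path of every member: the longest
#' common prefix of the members' lineages.
#'
#' @param db A `taxonomy_db`.
#' @param ids Non-empty vector of taxon ids present in `db`.
#' @return A single taxon id.
#' @export
lca <- function(db, ids) {
  ids <- unique(as.integer(ids))
  if (length(ids) == 0L) stop("lca: empty taxon set")
  common <- lineage(db, ids[[1L]])
  for (id in ids[-1L]) {
    lin <- lineage(db, id)
    k <- min(length(common), length(lin))
    eq <- common[seq_len(k)] == lin[seq_len(k)]
    common <- common[seq_len(if (all(eq)) k else which(!eq)[1L] - 1L)]
  }
  common[[length(common)]]
}

#' Names, ranks and ids along a lineage
#'
#' Convenience accessor used when mapping classified reads onto the taxonomy:
#' returns the root-first lineage of `id` as parallel name / rank / id vectors
#' ready for [build_tree()].
#'
#' @param db A `taxonomy_db`.
#' @param id A single taxon id.
#' @return `list(names = , ranks = , ids = )`.
#' @export
lineage_names <- function(db, id) {
  lin <- lineage(db, id)
  i <- taxon_index(db, lin)
  list(names = db$name[i], ranks = db$rank[i], ids = lin)
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat(sprintf("<taxonomy_db> %d taxa, root '%s' (id %d)%s\n",
              length(x$ids), x$name[match(x$root_id, x$ids)], x$root_id,
              if (is.null(x$merged)) "" else
                sprintf(", %d merged ids", length(x$merged))))
  invisible(x)
}
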