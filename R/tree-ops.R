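#' Collapse linear lineages (radix compression)
#'
#' Replaces every maximal chain of nodes that have exactly one child and no
#' directly assigned magnitude in any dataset by the deepest node of the
#' chain. Absorbed ancestors are recorded, root-to-leaf, in the survivor's
#' `collapsed` list so they stay searchable and can be re-expanded from the
#' stored lineage. The root is never absorbed, and no node with assigned
#' magnitude or with two or more children is ever removed, so every surviving
#' node's subtree total is unchanged.
#'
#' @param node Root `chart_node`.
#' @return The compressed tree.
#' @export
collapse_linear <- function(node) {
  if (length(node$children)) {
    node$children <- lapply(node$children, collapse_chain)
    names(node$children) <- vapply(node$children, `[[`, character(1), "name")
  }
  node
}

collapse_chain <- function(node) {
  absorbed <- list()
  while (length(node$children) == 1L && all(node$magnitude == 0)) {
    absorbed[[length(absorbed) + 1L]] <-
      list(name = node$name, rank = node$rank, taxon_id = node$taxon_id)
    node <- node$children[[1L]]
  }
  node$collapsed <- c(absorbed, node$collapsed)
  collapse_linear(node)
}

#' Summarize the tree at a maximum depth
#'
#' Nodes deeper than `max_depth` (the root has depth 1) are removed; their
#' subtree magnitudes are folded into the assigned magnitude of their
#' depth-`max_depth` ancestor and their attribute aggregates are merged
#' weight-proportionally, so the root total per dataset is conserved exactly.
#'
#' @param node Root `chart_node`.
#' @param max_depth Positive integer depth to keep.
#' @return The pruned tree.
#' @export
prune_depth <- function(node, max_depth) {
  if (!is.numeric(max_depth) || length(max_depth) != 1L || max_depth < 1) {
    stop("prune_depth: max_depth must be a positive integer")
  }
  if (is.infinite(max_depth)) return(node)
  prune_at(node, floor(max_depth), depth = 1L)
}

prune_at <- function(node, max_depth, depth) {
  if (depth == max_depth) {
    for (ch in node$children) {
      node$magnitude <- node$magnitude + magnitude_total(ch)
      node <- absorb_attributes(node, ch)
    }
    node$children <- list()
  } else {
    node$children <- lapply(node$children, prune_at, max_depth, depth + 1L)
  }
  node
}

## Merge all weighted-mean aggregates of `src`'s subtree into `dst`.
absorb_attributes <- function(dst, src) {
  for (a in names(src$attributes)) {
    agg <- src$attributes[[a]]
    if (is.character(agg)) next  # opaque text payloads are not merged upward
    cur <- dst$attributes[[a]]
    if (is.null(cur) || is.character(cur)) cur <- empty_aggregate(length(agg$weight))
    dst$attributes[[a]] <- merge_aggregates(cur, agg)
  }
  for (ch in src$children) dst <- absorb_attributes(dst, ch)
  dst
}

#' Sort siblings by decreasing magnitude
#'
#' Every sibling list is reordered by decreasing subtree total in the chosen
#' dataset; ties break lexicographically by name, case-insensitively, so
#' output order is deterministic across runs.
#'
#' @param node Root `chart_node`.
#' @param dataset Dataset index used for the ordering.
#' @return The sorted tree.
#' @export
sort_tree <- function(node, dataset = 1L) {
  if (length(node$children)) {
    totals <- vapply(node$children, magnitude_total, numeric(1), dataset)
    nms <- tolower(vapply(node$children, `[[`, character(1), "name"))
    node$children <- node$children[order(-totals, nms, method = "radix")]
    node$children <- lapply(node$children, sort_tree, dataset)
    names(node$children) <- vapply(node$children, `[[`, character(1), "name")
  }
  node
}

#' Search node names, honoring the visible depth
#'
#' Case-insensitive substring search over node names, including names absorbed
#' into `collapsed` lineages. Matches at or above `visible_depth` are reported
#' directly; a match hidden below the visible depth contributes its
#' depth-`visible_depth` ancestor instead, mirroring a display that highlights
#' both matching nodes and visible nodes containing hidden matches.
#'
#' @param node Root `chart_node`.
#' @param query Non-empty search string (fixed substring, not a regex).
#' @param visible_depth Deepest displayed level (root = depth 1).
#' @return `list(matched = , hidden_ancestors = )`, both character vectors of
#'   `/`-joined node paths from the root.
#' @export
search_tree <- function(node, query, visible_depth = Inf) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop("search_tree: query must be a non-empty string")
  }
  if (visible_depth < 1) stop("search_tree: visible_depth must be >= 1")
  q <- tolower(query)
  matched <- character(0)
  hidden <- character(0)
  walk <- function(n, path, depth, visible_ancestor) {
    path <- c(path, n$name)
    here <- if (depth <= visible_depth) paste(path, collapse = "/") else visible_ancestor
    if (depth <= visible_depth) visible_ancestor <- here
    names_here <- c(n$name,
                    vapply(n$collapsed, `[[`, character(1), "name"))
    if (any(grepl(q, tolower(names_here), fixed = TRUE))) {
      if (depth <= visible_depth) {
        matched <<- c(matched, here)
      } else {
        hidden <<- c(hidden, visible_ancestor)
      }
    }
    for (ch in n$children) walk(ch, path, depth + 1L, visible_ancestor)
  }
  walk(node, character(0), 1L, NA_character_)
  list(matched = unique(matched), hidden_ancestors = unique(hidden))
}

#' Locate a node by name
#'
#' Exact, case-insensitive match on node names (including collapsed lineage
#' names), used to resolve zoom targets. Errors if the name is ambiguous,
#' listing all candidate paths.
#'
#' @param node Root `chart_node`.
#' @param name Node name to resolve.
#' @return The `/`-joined path of the unique match.
#' @export
find_node_path <- function(node, name) {
  target <- tolower(name)
  hits <- character(0)
  walk <- function(n, path) {
    path <- c(path, n$name)
    nm <- c(n$name, vapply(n$collapsed, `[[`, character(1), "name"))
    if (target %in% tolower(nm)) hits <<- c(hits, paste(path, collapse = "/"))
    for (ch in n$children) walk(ch, path)
  }
  walk(node, character(0))
  if (length(hits) == 0L) stop(sprintf("node '%s' not found", name))
  if (length(hits) > 1L) {
    stop(sprintf("node name '%s' is ambiguous; candidates: %s",
                 name, paste(hits, collapse = ", ")))
  }
  hits
}

## Return the subtree rooted at a /-joined path (root name first).
subtree_at <- function(node, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1L]]
  if (parts[[1L]] != node$name) stop(sprintf("path '%s' does not start at the root", path))
  for (p in parts[-1L]) {
    node <- node$children[[p]]
    if (is.null(node)) stop(sprintf("path '%s' not found", path))
  }
  node
}
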