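#' Create a chart node
#'
#' A chart node is one vertex of the quantitative hierarchy: it carries a
#' display name, an optional taxonomic rank and taxon id, a per-dataset vector
#' of magnitudes assigned *directly* to the node (reads classified exactly
#' here, as opposed to a descendant), per-dataset attribute aggregates, an
#' ordered list of children, and the lineage absorbed by radix compression.
#'
#' @param name Node label (scientific name or free text).
#' @param n_datasets Number of datasets stored in the chart.
#' @param rank Optional rank label (e.g. "genus").
#' @param taxon_id Optional integer taxon id.
#' @return An object of class `chart_node`.
#' @export
chart_node <- function(name, n_datasets = 1L, rank = NA_character_,
                       taxon_id = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(
    name      = name,
    rank      = as.character(rank),
    taxon_id  = as.integer(taxon_id),
    magnitude = numeric(n_datasets),
    attributes = list(),
    collapsed  = list(),
    children   = list()
  ), class = "chart_node")
}

#' Total subtree magnitude of a node
#'
#' The node's own assigned magnitude plus the totals of all children, per
#' dataset. This is the quantity an angular sweep is proportional to.
#'
#' @param node A `chart_node`.
#' @param dataset Dataset index, or `NULL` for the full per-dataset vector.
#' @return Numeric scalar (if `dataset` given) or vector.
#' @export
magnitude_total <- function(node, dataset = NULL) {
  tot <- node$magnitude
  for (ch in node$children) tot <- tot + magnitude_total(ch)
  if (is.null(dataset)) tot else tot[[dataset]]
}

## Weighted-mean aggregate: list(mean = numeric(n), weight = numeric(n)),
## one slot per dataset; weight 0 means "no observation".
empty_aggregate <- function(n_datasets) {
  list(mean = numeric(n_datasets), weight = numeric(n_datasets))
}

## Fold one (value, weight) observation into an aggregate at dataset d.
update_aggregate <- function(agg, value, weight, d) {
  w0 <- agg$weight[d]
  w1 <- w0 + weight
  agg$mean[d] <- if (w1 > 0) (agg$mean[d] * w0 + value * weight) / w1 else 0
  agg$weight[d] <- w1
  agg
}

## Merge two aggregates weight-proportionally (vectorized over datasets).
merge_aggregates <- function(a, b) {
  w <- a$weight + b$weight
  m <- ifelse(w > 0, (a$mean * a$weight + b$mean * b$weight) / w, 0)
  list(mean = m, weight = w)
}

#' Weighted mean with total weight
#'
#' Aggregates attribute observations as a magnitude-weighted mean, the form in
#' which per-node attributes (confidence, log e-value, percent identity) are
#' stored and later merged. Merging two pre-aggregated groups with
#' [merge_aggregates()] is exactly equivalent to aggregating the pooled
#' observations.
#'
#' @param values Numeric observations.
#' @param weights Positive weights, same length.
#' @return `list(mean = , weight = )`.
#' @export
aggregate_attribute <- function(values, weights) {
  if (length(values) == 0L) stop("aggregate_attribute: empty input")
  if (length(values) != length(weights)) {
    stop("aggregate_attribute: values and weights differ in length")
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("aggregate_attribute: weights must be positive and finite")
  }
  list(mean = sum(values * weights) / sum(weights), weight = sum(weights))
}

## Fold an attribute observation into a node, creating the slot on demand.
node_add_attribute <- function(node, attr_name, value, weight, dataset,
                               n_datasets) {
  agg <- node$attributes[[attr_name]]
  if (is.null(agg)) agg <- empty_aggregate(n_datasets)
  node$attributes[[attr_name]] <- update_aggregate(agg, value, weight, dataset)
  node
}

## Insert one assignment (lineage below the root) into the tree.
insert_assignment <- function(node, lineage, magnitude, dataset, n_datasets,
                              attributes = NULL, lineage_attributes = NULL,
                              ranks = NULL, taxon_ids = NULL, level = 0L) {
  if (length(lineage) == 0L) {
    node$magnitude[dataset] <- node$magnitude[dataset] + magnitude
    for (a in names(attributes)) {
      node <- node_add_attribute(node, a, attributes[[a]], magnitude,
                                 dataset, n_datasets)
    }
    return(node)
  }
  nm <- lineage[[1L]]
  child <- node$children[[nm]]
  if (is.null(child)) {
    child <- chart_node(nm, n_datasets,
                        rank     = if (!is.null(ranks)) ranks[[1L]] else NA,
                        taxon_id = if (!is.null(taxon_ids)) taxon_ids[[1L]] else NA)
  }
  for (a in names(lineage_attributes)) {
    v <- lineage_attributes[[a]][[1L]]
    if (!is.na(v)) {
      child <- node_add_attribute(child, a, v, magnitude, dataset, n_datasets)
    }
  }
  node$children[[nm]] <- insert_assignment(
    child, lineage[-1L], magnitude, dataset, n_datasets,
    attributes = attributes,
    lineage_attributes = lapply(lineage_attributes, function(x) x[-1L]),
    ranks = if (!is.null(ranks)) ranks[-1L],
    taxon_ids = if (!is.null(taxon_ids)) taxon_ids[-1L]
  )
  node
}

#' Build a quantitative tree from lineage assignments
#'
#' Each assignment is a list with a `lineage` (character vector, root level
#' first), a non-negative `magnitude` (default 1), optional terminal
#' `attributes` (named numeric values aggregated at the lineage's last node as
#' magnitude-weighted means), optional `lineage_attributes` (named list of
#' numeric vectors parallel to the lineage, aggregated at every level — used
#' for per-rank classifier confidences), and optional `ranks` / `taxon_ids`
#' vectors parallel to the lineage.
#'
#' If every lineage starts with the same name, that node becomes the root;
#' otherwise a synthetic root named `root_name` is created above them.
#' Repeated lineages accumulate; shared prefixes share nodes.
#'
#' @param assignments Non-empty list of assignment lists.
#' @param n_datasets Number of datasets the chart will hold.
#' @param dataset Dataset index these assignments belong to.
#' @param root_name Root label when a synthetic root is needed (default
#'   `"root"`), or to force a named root above all lineages.
#' @return The root `chart_node`.
#' @export
build_tree <- function(assignments, n_datasets = 1L, dataset = 1L,
                       root_name = NULL) {
  if (length(assignments) == 0L) stop("build_tree: empty assignment list")
  mags <- vapply(assignments, function(a) {
    m <- a$magnitude
    if (is.null(m)) 1 else as.numeric(m)
  }, numeric(1))
  if (any(!is.finite(mags)) || any(mags < 0)) {
    stop("build_tree: magnitudes must be finite and non-negative")
  }
  lens <- vapply(assignments, function(a) length(a$lineage), integer(1))
  if (any(lens == 0L)) stop("build_tree: every assignment needs a lineage")

  firsts <- vapply(assignments, function(a) a$lineage[[1L]], character(1))
  shared_root <- is.null(root_name) && length(unique(firsts)) == 1L
  root <- if (shared_root) {
    a1 <- assignments[[1L]]
    chart_node(firsts[[1L]], n_datasets,
               rank     = if (!is.null(a1$ranks)) a1$ranks[[1L]] else NA,
               taxon_id = if (!is.null(a1$taxon_ids)) a1$taxon_ids[[1L]] else NA)
  } else {
    chart_node(if (is.null(root_name)) "root" else root_name, n_datasets)
  }

  for (i in seq_along(assignments)) {
    a <- assignments[[i]]
    lin <- as.character(a$lineage)
    ranks <- a$ranks
    taxa  <- a$taxon_ids
    lattr <- a$lineage_attributes
    if (shared_root) {
      # root-level lineage attribute lands on the root itself
      for (nm in names(lattr)) {
        v <- lattr[[nm]][[1L]]
        if (!is.na(v)) {
          root <- node_add_attribute(root, nm, v, mags[i], dataset, n_datasets)
        }
      }
      lin <- lin[-1L]
      if (!is.null(ranks)) ranks <- ranks[-1L]
      if (!is.null(taxa))  taxa  <- taxa[-1L]
      lattr <- lapply(lattr, function(x) x[-1L])
    }
    root <- insert_assignment(root, lin, mags[i], dataset, n_datasets,
                              attributes = a$attributes,
                              lineage_attributes = lattr,
                              ranks = ranks, taxon_ids = taxa)
  }
  root
}

#' Assemble a chart
#'
#' A chart bundles the tree with dataset names, attribute definitions and
#' display settings. All per-dataset vectors in the tree must have length
#' `length(dataset_names)`.
#'
#' @param root Root `chart_node`.
#' @param dataset_names Character vector of dataset labels.
#' @param attribute_defs List of definitions from [attribute_def()].
#' @param max_depth Depth cap applied at render time (`Inf` = unlimited).
#' @param collapse Whether linear lineages are collapsed at render time.
#' @return An object of class `taxburst_chart`.
#' @export
chart <- function(root, dataset_names = "dataset 1", attribute_defs = list(),
                  max_depth = Inf, collapse = TRUE) {
  stopifnot(inherits(root, "chart_node"))
  if (length(root$magnitude) != length(dataset_names)) {
    stop("chart: dataset_names length does not match the tree's dataset count")
  }
  if (!is.infinite(max_depth) && (max_depth < 1 || max_depth != floor(max_depth))) {
    stop("chart: max_depth must be a positive integer or Inf")
  }
  structure(list(
    root = root,
    dataset_names = as.character(dataset_names),
    attribute_defs = attribute_defs,
    settings = list(max_depth = max_depth, collapse = isTRUE(collapse))
  ), class = "taxburst_chart")
}

#' Define a chart attribute
#'
#' @param name Internal attribute key as stored on nodes.
#' @param display Human-readable label (legend / summaries).
#' @param aggregation `"weighted-mean"` for numeric aggregates, `"none"` for
#'   opaque text payloads (e.g. HTML snippets carried through the XML).
#' @param gradient Optional [gradient_spec()] used when coloring by this
#'   attribute.
#' @return A list of class `attribute_def`.
#' @export
attribute_def <- function(name, display = name,
                          aggregation = c("weighted-mean", "none"),
                          gradient = NULL) {
  aggregation <- match.arg(aggregation)
  structure(list(name = name, display = display, aggregation = aggregation,
                 gradient = gradient), class = "attribute_def")
}

## Subtree-merged aggregate for one attribute (display/coloring view).
rollup_attribute <- function(node, attr_name, n_datasets) {
  agg <- node$attributes[[attr_name]]
  if (is.null(agg) || is.character(agg)) agg <- empty_aggregate(n_datasets)
  for (ch in node$children) {
    agg <- merge_aggregates(agg, rollup_attribute(ch, attr_name, n_datasets))
  }
  agg
}

count_nodes <- function(node) {
  1L + sum(vapply(node$children, count_nodes, integer(1)))
}

tree_height <- function(node) {
  if (length(node$children) == 0L) return(1L)
  1L + max(vapply(node$children, tree_height, integer(1)))
}

#' @export
print.chart_node <- function(x, ...) {
  cat(sprintf("<chart_node> %s (%d nodes, height %d, total %s)\n",
              x$name, count_nodes(x), tree_height(x),
              paste(format_magnitude(magnitude_total(x)), collapse = " / ")))
  invisible(x)
}

#' @export
print.taxburst_chart <- function(x, ...) {
  cat(sprintf("<taxburst_chart> root '%s': %d nodes, height %d\n",
              x$root$name, count_nodes(x$root), tree_height(x$root)))
  cat(sprintf("  datasets:   %s\n", paste(x$dataset_names, collapse = ", ")))
  tot <- magnitude_total(x$root)
  cat(sprintf("  totals:     %s\n",
              paste(vapply(tot, format_magnitude, character(1)), collapse = ", ")))
  if (length(x$attribute_defs)) {
    cat(sprintf("  attributes: %s\n",
                paste(vapply(x$attribute_defs, `[[`, character(1), "name"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.taxburst_chart <- function(object, dataset = 1L, ...) {
  root <- object$root
  leaves <- function(n) if (length(n$children) == 0L) 1L else
    sum(vapply(n$children, leaves, integer(1)))
  out <- list(
    nodes = count_nodes(root), height = tree_height(root),
    leaves = leaves(root),
    total_magnitude = magnitude_total(root, dataset),
    datasets = object$dataset_names
  )
  class(out) <- "summary.taxburst_chart"
  out
}

#' @export
print.summary.taxburst_chart <- function(x, ...) {
  cat(sprintf("chart: %d nodes (%d leaves), height %d\n",
              x$nodes, x$leaves, x$height))
  cat(sprintf("total magnitude: %s (dataset 1 of %d)\n",
              format_magnitude(x$total_magnitude), length(x$datasets)))
  invisible(x)
}
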