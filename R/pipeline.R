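#' Build a chart from raw BLAST tabular hits
#'
#' Full classification pipeline: parse the tabular hits, classify each query
#' to the lowest common ancestor of its top-scoring alignments, optionally
#' weight queries by per-sequence magnitudes (e.g. reads per contig), map the
#' assignments onto the taxonomy's lineages and accumulate them into a chart.
#' Nodes carry `avg_log_evalue` and `identity` aggregates with matching
#' gradient definitions (for e-values, low/most-negative is the most
#' significant and colored green; high is red).
#'
#' @param hits_path BLAST tabular file (12 columns).
#' @param taxonomy A `taxonomy_db`, or a directory containing
#'   `nodes.dmp` / `names.dmp`.
#' @param taxon_map Named subject->taxon map, a path to a two-column TSV, or
#'   `NULL` when subjects are already taxon ids.
#' @param score_factor Bit-score tie tolerance for [select_top_hits()].
#' @param magnitudes Named query->magnitude vector, or a path to an ACE file.
#' @param dataset_name Label for the single dataset.
#' @param strict Error (rather than skip) on unresolvable subject taxa.
#' @return A `taxburst_chart`.
#' @export
chart_from_blast <- function(hits_path, taxonomy, taxon_map = NULL,
                             score_factor = 1, magnitudes = NULL,
                             dataset_name = "dataset 1", strict = FALSE) {
  db <- if (inherits(taxonomy, "taxonomy_db")) taxonomy else {
    load_taxonomy(file.path(taxonomy, "nodes.dmp"),
                  file.path(taxonomy, "names.dmp"),
                  merged_path = {
                    m <- file.path(taxonomy, "merged.dmp")
                    if (file.exists(m)) m else NULL
                  })
  }
  if (is.character(taxon_map) && length(taxon_map) == 1L && file.exists(taxon_map)) {
    tm <- utils::read.table(taxon_map, sep = "\t", header = FALSE,
                            colClasses = c("character", "integer"))
    taxon_map <- stats::setNames(tm[[2L]], tm[[1L]])
  }
  groups <- read_blast_tabular(hits_path, taxon_map)
  res <- classify_hits(groups, db, score_factor, strict)
  if (length(res$assignments) == 0L) {
    stop(sprintf("%s: no queries could be classified", hits_path))
  }
  if (!is.null(magnitudes)) {
    if (is.character(magnitudes) && length(magnitudes) == 1L) {
      magnitudes <- read_ace_magnitudes(magnitudes)
    }
    res$assignments <- apply_magnitudes(res$assignments, magnitudes)
  }
  root <- build_tree(assignments_to_lineages(res$assignments, db))
  ch <- chart(root, dataset_names = dataset_name, attribute_defs = list(
    attribute_def("avg_log_evalue", "Avg. log e-value",
                  gradient = gradient_spec("avg_log_evalue",
                                           low = "#00cc00", high = "#ff0000")),
    attribute_def("identity", "Avg. % identity",
                  gradient = gradient_spec("identity"))
  ))
  ch$n_classified <- length(res$assignments)
  ch$n_skipped <- res$skipped
  ch
}

#' Build a chart from a lineage + magnitude text file
#'
#' @param path Input file for [read_text_lineage()].
#' @param dataset_name Dataset label.
#' @return A `taxburst_chart`.
#' @export
chart_from_text <- function(path, dataset_name = "dataset 1") {
  chart(build_tree(read_text_lineage(path)), dataset_names = dataset_name)
}

#' Build a chart from RDP-Classifier-style assignments
#'
#' Per-rank confidences are aggregated (magnitude-weighted) at every named
#' node of each read's lineage and exposed as a `confidence` attribute with a
#' low-red / high-green gradient.
#'
#' @param path Input file for [read_rdp()].
#' @param dataset_name Dataset label.
#' @return A `taxburst_chart`.
#' @export
chart_from_rdp <- function(path, dataset_name = "dataset 1") {
  confidence_chart(read_rdp(path), dataset_name)
}

#' Build a chart from PhymmBL-style assignments
#'
#' @param path Input file for [read_phymmbl()].
#' @param dataset_name Dataset label.
#' @return A `taxburst_chart`.
#' @export
chart_from_phymmbl <- function(path, dataset_name = "dataset 1") {
  confidence_chart(read_phymmbl(path), dataset_name)
}

confidence_chart <- function(assignments, dataset_name) {
  # classifier lineages start at a rank (domain/phylum), not at a root:
  # always wrap them so sibling domains stay comparable under one root
  chart(build_tree(assignments, root_name = "root"),
        dataset_names = dataset_name,
        attribute_defs = list(
          attribute_def("confidence", "Avg. confidence",
                        gradient = gradient_spec("confidence",
                                                 domain = c(0, 1)))))
}

#' Render a chart to SVG
#'
#' Applies the display pipeline — optional radix compression, optional depth
#' summarization, magnitude sorting, optional polar zoom onto a focus node —
#' then lays out angles and radii, colors nodes (recursive HSL hues by
#' default, or a value gradient with `color_by`), places labels, and renders
#' the SVG document.
#'
#' @param chart A `taxburst_chart` or a path to a chart XML file.
#' @param out_svg Optional output path; when given the SVG is written there.
#' @param max_depth Depth cap (root = depth 1); `NULL` uses the chart setting.
#' @param collapse Collapse linear lineages; `NULL` uses the chart setting.
#' @param color_by Attribute name to color by (gradient), or `NULL` for HSL
#'   hues.
#' @param dataset Dataset index to display.
#' @param zoom Name of a node to zoom onto (unique, case-insensitive match;
#'   ambiguity is an error listing the candidates), drawn at full zoom.
#' @param start_angle Root start angle in degrees, clockwise from 12 o'clock.
#' @param canvas_px Canvas edge in pixels.
#' @param full_label_depth,compression Radial band parameters, see
#'   [compute_radii()].
#' @param font_px Label font size.
#' @return The SVG text, invisibly.
#' @export
render_chart <- function(chart, out_svg = NULL, max_depth = NULL,
                         collapse = NULL, color_by = NULL, dataset = 1L,
                         zoom = NULL, start_angle = 0, canvas_px = 800,
                         full_label_depth = 3, compression = 0.7,
                         font_px = 11) {
  if (is.character(chart)) chart <- read_chart_xml(chart)
  stopifnot(inherits(chart, "taxburst_chart"))
  if (is.null(max_depth)) max_depth <- chart$settings$max_depth
  if (is.null(collapse)) collapse <- chart$settings$collapse
  n_datasets <- length(chart$dataset_names)

  root <- chart$root
  breadcrumb <- root$name
  if (isTRUE(collapse)) root <- collapse_linear(root)
  if (!is.infinite(max_depth)) root <- prune_depth(root, max_depth)
  root <- sort_tree(root, dataset)
  if (!is.null(zoom)) {
    path <- find_node_path(root, zoom)
    breadcrumb <- strsplit(path, "/", fixed = TRUE)[[1L]]
    root <- subtree_at(root, path)
  }

  sectors <- compute_angles(root, dataset, start_angle)
  sectors <- compute_radii(sectors, full_label_depth = full_label_depth,
                           compression = compression)

  legend <- NULL
  if (is.null(color_by)) {
    hues <- assign_hues(root, dataset, depth_for_lightness = max(sectors$depth))
    colors <- data.frame(path = hues$path,
                         color = hsl_to_hex(hues$hue, hues$saturation,
                                            hues$lightness),
                         stringsAsFactors = FALSE)
  } else {
    def <- Filter(function(d) d$name == color_by, chart$attribute_defs)
    spec <- if (length(def)) def[[1L]]$gradient else NULL
    if (is.null(spec)) spec <- gradient_spec(color_by)
    vals <- node_gradient_values(root, color_by, dataset, n_datasets)
    if (is.null(spec$domain)) {
      obs <- vals$value[!is.na(vals$value)]
      if (length(obs) == 0L) {
        stop(sprintf("render_chart: no values for attribute '%s'", color_by))
      }
      spec$domain <- if (min(obs) < max(obs)) range(obs) else c(min(obs), min(obs) + 1)
    }
    colors <- data.frame(
      path = vals$path,
      color = ifelse(is.na(vals$value), "#bbbbbb",
                     gradient_color(ifelse(is.na(vals$value), spec$domain[[1L]],
                                           vals$value), spec)),
      stringsAsFactors = FALSE)
    legend <- spec
  }

  labels <- place_labels(sectors, canvas_radius_px = canvas_px / 2,
                         font_px = font_px)
  svg <- render_svg(sectors, colors, labels = labels, legend = legend,
                    summary = breadcrumb, canvas_px = canvas_px,
                    font_px = font_px)
  if (!is.null(out_svg)) writeLines(svg, out_svg)
  invisible(svg)
}

## Subtree-rolled attribute value per node, in layout path coordinates.
node_gradient_values <- function(root, attr_name, dataset, n_datasets) {
  rows <- list()
  walk <- function(node, path) {
    path <- if (nzchar(path)) paste(path, node$name, sep = "/") else node$name
    agg <- rollup_attribute(node, attr_name, n_datasets)
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path,
      value = if (agg$weight[[dataset]] > 0) agg$mean[[dataset]] else NA_real_,
      stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, path)
  }
  walk(root, "")
  do.call(rbind, rows)
}

#' @export
plot.taxburst_chart <- function(x, ...) {
  svg <- render_chart(x, ...)
  message("render_chart() produced an SVG document; write it with out_svg= ",
          "or render_html() to view it in a browser")
  invisible(svg)
}
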