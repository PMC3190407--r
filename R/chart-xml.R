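## Chart XML schema (version 1.0)
##
## <chart schema="1.0">
##   <datasets><dataset>name</dataset>...</datasets>
##   <attributes>
##     <attributedef name=".." display=".." aggregation="weighted-mean|none">
##       <gradient low="#rrggbb" high="#rrggbb" [min=".." max=".."]/>
##     </attributedef>...
##   </attributes>
##   <settings maxDepth="6|unlimited" collapse="true|false"/>
##   <node name=".." [rank=".."] [taxonId=".."]>
##     <magnitude>v1 v2 ...</magnitude>              (one value per dataset)
##     [<collapsed><ancestor name=".." .../></collapsed>]
##     [<attribute name=".." mean="m1 m2.." weight="w1 w2.."/>]   (aggregate)
##     [<attribute name=".."><![text payload]></attribute>]       (opaque)
##     [<node>...</node>...]
##   </node>
## </chart>
##
## Numbers are serialized with "%.17g" so doubles round-trip exactly.

fmt_num <- function(x) sprintf("%.17g", x)
fmt_vec <- function(x) paste(fmt_num(x), collapse = " ")
parse_vec <- function(s) as.numeric(strsplit(trimws(s), " ", fixed = TRUE)[[1L]])

#' Write a chart to its XML document
#'
#' Serializes the full chart model — tree shape, per-dataset magnitudes,
#' collapsed lineages, attribute aggregates and definitions, settings — so
#' that [read_chart_xml()] reproduces it exactly.
#'
#' @param chart A `taxburst_chart`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chart_xml <- function(chart, path) {
  stopifnot(inherits(chart, "taxburst_chart"))
  doc <- xml2::xml_new_root("chart", schema = "1.0")
  ds <- xml2::xml_add_child(doc, "datasets")
  for (d in chart$dataset_names) xml2::xml_add_child(ds, "dataset", d)
  at <- xml2::xml_add_child(doc, "attributes")
  for (def in chart$attribute_defs) {
    el <- xml2::xml_add_child(at, "attributedef", name = def$name,
                              display = def$display,
                              aggregation = def$aggregation)
    g <- def$gradient
    if (!is.null(g)) {
      ge <- xml2::xml_add_child(el, "gradient", low = g$low, high = g$high)
      if (!is.null(g$domain)) {
        xml2::xml_set_attr(ge, "min", fmt_num(g$domain[[1L]]))
        xml2::xml_set_attr(ge, "max", fmt_num(g$domain[[2L]]))
      }
    }
  }
  md <- chart$settings$max_depth
  xml2::xml_add_child(doc, "settings",
                      maxDepth = if (is.infinite(md)) "unlimited" else fmt_num(md),
                      collapse = tolower(as.character(chart$settings$collapse)))
  write_node_xml(doc, chart$root)
  xml2::write_xml(doc, path)
  invisible(path)
}

write_node_xml <- function(parent, node) {
  el <- xml2::xml_add_child(parent, "node", name = node$name)
  if (!is.na(node$rank)) xml2::xml_set_attr(el, "rank", node$rank)
  if (!is.na(node$taxon_id)) xml2::xml_set_attr(el, "taxonId", as.character(node$taxon_id))
  xml2::xml_add_child(el, "magnitude", fmt_vec(node$magnitude))
  if (length(node$collapsed)) {
    co <- xml2::xml_add_child(el, "collapsed")
    for (a in node$collapsed) {
      ae <- xml2::xml_add_child(co, "ancestor", name = a$name)
      if (!is.na(a$rank)) xml2::xml_set_attr(ae, "rank", a$rank)
      if (!is.na(a$taxon_id)) xml2::xml_set_attr(ae, "taxonId", as.character(a$taxon_id))
    }
  }
  for (nm in names(node$attributes)) {
    v <- node$attributes[[nm]]
    if (is.character(v)) {
      xml2::xml_add_child(el, "attribute", v, name = nm)
    } else {
      xml2::xml_add_child(el, "attribute", name = nm,
                          mean = fmt_vec(v$mean), weight = fmt_vec(v$weight))
    }
  }
  for (ch in node$children) write_node_xml(el, ch)
  el
}

#' Read a chart XML document
#'
#' Inverse of [write_chart_xml()]; schema violations raise errors naming the
#' offending element path.
#'
#' @param path Path to a chart XML file.
#' @return A `taxburst_chart`.
#' @export
read_chart_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "chart") {
    stop(sprintf("%s: root element is <%s>, expected <chart>", path, xml2::xml_name(doc)))
  }
  datasets <- xml2::xml_text(xml2::xml_find_all(doc, "./datasets/dataset"))
  if (length(datasets) == 0L) stop(sprintf("%s: /chart/datasets is empty", path))

  defs <- lapply(xml2::xml_find_all(doc, "./attributes/attributedef"), function(el) {
    g <- xml2::xml_find_first(el, "./gradient")
    grad <- NULL
    if (!inherits(g, "xml_missing")) {
      dom <- NULL
      mn <- xml2::xml_attr(g, "min")
      if (!is.na(mn)) dom <- c(as.numeric(mn), as.numeric(xml2::xml_attr(g, "max")))
      grad <- gradient_spec(attribute = xml2::xml_attr(el, "name"),
                            low = xml2::xml_attr(g, "low"),
                            high = xml2::xml_attr(g, "high"),
                            domain = dom)
    }
    attribute_def(xml2::xml_attr(el, "name"),
                  display = xml2::xml_attr(el, "display"),
                  aggregation = xml2::xml_attr(el, "aggregation"),
                  gradient = grad)
  })

  st <- xml2::xml_find_first(doc, "./settings")
  if (inherits(st, "xml_missing")) stop(sprintf("%s: missing /chart/settings", path))
  md_raw <- xml2::xml_attr(st, "maxDepth")
  max_depth <- if (is.na(md_raw) || md_raw == "unlimited") Inf else as.numeric(md_raw)
  collapse <- identical(xml2::xml_attr(st, "collapse"), "true")

  root_el <- xml2::xml_find_first(doc, "./node")
  if (inherits(root_el, "xml_missing")) stop(sprintf("%s: missing /chart/node", path))
  root <- read_node_xml(root_el, n_datasets = length(datasets),
                        where = "/chart/node")
  chart(root, dataset_names = datasets, attribute_defs = defs,
        max_depth = max_depth, collapse = collapse)
}

read_node_xml <- function(el, n_datasets, where) {
  nm <- xml2::xml_attr(el, "name")
  if (is.na(nm) || !nzchar(nm)) stop(sprintf("%s: node without a name", where))
  node <- chart_node(nm, n_datasets,
                     rank = xml2::xml_attr(el, "rank"),
                     taxon_id = attr_int(el, "taxonId"))
  mag_el <- xml2::xml_find_first(el, "./magnitude")
  if (inherits(mag_el, "xml_missing")) {
    stop(sprintf("%s: missing <magnitude>", where))
  }
  mag <- parse_vec(xml2::xml_text(mag_el))
  if (length(mag) != n_datasets || anyNA(mag)) {
    stop(sprintf("%s: magnitude has %d value(s), chart declares %d dataset(s)",
                 where, length(mag), n_datasets))
  }
  if (any(mag < 0)) stop(sprintf("%s: negative magnitude", where))
  node$magnitude <- mag

  node$collapsed <- lapply(xml2::xml_find_all(el, "./collapsed/ancestor"),
    function(a) list(name = xml2::xml_attr(a, "name"),
                     rank = xml2::xml_attr(a, "rank"),
                     taxon_id = attr_int(a, "taxonId")))

  for (ael in xml2::xml_find_all(el, "./attribute")) {
    a_name <- xml2::xml_attr(ael, "name")
    mean_raw <- xml2::xml_attr(ael, "mean")
    if (is.na(mean_raw)) {
      node$attributes[[a_name]] <- xml2::xml_text(ael)
    } else {
      m <- parse_vec(mean_raw)
      w <- parse_vec(xml2::xml_attr(ael, "weight"))
      if (length(m) != n_datasets || length(w) != n_datasets) {
        stop(sprintf("%s: attribute '%s' aggregate length mismatch", where, a_name))
      }
      node$attributes[[a_name]] <- list(mean = m, weight = w)
    }
  }

  kids <- xml2::xml_find_all(el, "./node")
  for (k in seq_along(kids)) {
    ch <- read_node_xml(kids[[k]], n_datasets,
                        where = sprintf("%s/node[%d]", where, k))
    if (ch$name %in% names(node$children)) {
      stop(sprintf("%s: duplicate child name '%s'", where, ch$name))
    }
    node$children[[ch$name]] <- ch
  }
  node
}

attr_int <- function(el, name) {
  v <- xml2::xml_attr(el, name)
  if (is.na(v)) NA_integer_ else as.integer(v)
}
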