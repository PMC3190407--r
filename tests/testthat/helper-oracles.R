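# Shared generators and independent oracles. The oracles deliberately avoid
# the package's code paths: subtree sums, LCA and hue ranges are recomputed
# here from first principles so tests compare two separate derivations.

# Random chart tree built directly from a random parent vector.
random_tree <- function(n_nodes, n_datasets = 1L, seed = 1L,
                        integer_mag = TRUE, p_zero = 0.3, max_children = 4L) {
  set.seed(seed)
  parent <- integer(n_nodes)
  n_children <- integer(n_nodes)
  parent[1L] <- 0L
  for (i in seq_len(n_nodes)[-1L]) {
    open <- which(n_children[seq_len(i - 1L)] < max_children)
    p <- open[sample.int(length(open), 1L)]
    parent[i] <- p
    n_children[p] <- n_children[p] + 1L
  }
  # mixed-case names exercise the case-insensitive tie-break
  nm <- sprintf("%s%d", sample(c("node", "Node", "NODE"), n_nodes, TRUE),
                seq_len(n_nodes))
  mags <- matrix(0, n_nodes, n_datasets)
  for (d in seq_len(n_datasets)) {
    v <- if (integer_mag) stats::rpois(n_nodes, 5) else stats::runif(n_nodes, 0, 10)
    v[stats::runif(n_nodes) < p_zero] <- 0
    mags[, d] <- v
  }
  build <- function(i) {
    nd <- chart_node(nm[i], n_datasets)
    nd$magnitude <- mags[i, ]
    for (j in which(parent == i)) nd$children[[nm[j]]] <- build(j)
    nd
  }
  build(1L)
}

# Flat table of (path, depth, assigned magnitude, subtree total) computed by
# an independent bottom-up recursion over the chosen dataset.
oracle_tree_table <- function(node, dataset = 1L) {
  rows <- list()
  walk <- function(n, path, depth) {
    path <- if (nzchar(path)) paste(path, n$name, sep = "/") else n$name
    total <- n$magnitude[[dataset]]
    for (ch in n$children) total <- total + walk(ch, path, depth + 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path, depth = depth, assigned = n$magnitude[[dataset]],
      total = total, stringsAsFactors = FALSE)
    total
  }
  walk(node, "", 1L)
  do.call(rbind, rows)
}

# Sum of every assigned magnitude in the tree, per dataset (conservation
# oracle: magnitude_total(root) must equal this).
oracle_assigned_sum <- function(node) {
  s <- node$magnitude
  for (ch in node$children) s <- s + oracle_assigned_sum(ch)
  s
}

# Brute-force LCA: intersect full root-paths, take the deepest member.
oracle_lca <- function(db, ids) {
  root_path <- function(id) {
    p <- id
    while (id != db$root_id) {
      id <- db$parent[[match(id, db$ids)]]
      p <- c(p, id)
    }
    p
  }
  paths <- lapply(unique(ids), root_path)
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(x) length(root_path(x)), integer(1))
  common[[which.max(depths)]]
}

# Brute-force top-hit filter + LCA for one query's hit table.
oracle_classify <- function(hits, db, score_factor) {
  keep <- hits$bit_score >= score_factor * max(hits$bit_score)
  taxa <- hits$subject_taxon[keep]
  taxa <- taxa[!is.na(taxa) & taxa %in% db$ids]
  if (length(taxa) == 0L) return(NA_integer_)
  oracle_lca(db, taxa)
}

# Independent iterative recomputation of the hue ranges: a queue-driven
# breadth-first pass using its own subtree sums, equal split at the root and
# magnitude-weighted splits below.
oracle_hue_ranges <- function(root, dataset = 1L, hue_range = c(0, 360)) {
  subtree_sum <- function(n) {
    s <- n$magnitude[[dataset]]
    for (ch in n$children) s <- s + subtree_sum(ch)
    s
  }
  rows <- list()
  queue <- list(list(node = root, lo = hue_range[[1L]], hi = hue_range[[2L]],
                     path = root$name, at_root = TRUE))
  while (length(queue)) {
    it <- queue[[1L]]; queue <- queue[-1L]
    rows[[length(rows) + 1L]] <- data.frame(
      path = it$path, hue_lo = it$lo, hue_hi = it$hi, stringsAsFactors = FALSE)
    kids <- it$node$children
    if (!length(kids)) next
    if (it$at_root) {
      widths <- rep((it$hi - it$lo) / length(kids), length(kids))
    } else {
      w <- vapply(kids, subtree_sum, numeric(1))
      widths <- if (sum(w) > 0) (it$hi - it$lo) * w / sum(w) else
        rep((it$hi - it$lo) / length(kids), length(kids))
    }
    lo <- it$lo
    for (k in seq_along(kids)) {
      queue[[length(queue) + 1L]] <- list(
        node = kids[[k]], lo = lo, hi = lo + widths[[k]],
        path = paste(it$path, kids[[k]]$name, sep = "/"), at_root = FALSE)
      lo <- lo + widths[[k]]
    }
  }
  do.call(rbind, rows)
}

# A small fixed taxonomy written in the NCBI dump dialect:
#   1 root -> 2 superkingdom -> 10 genus -> {11, 12} species
#            \-> 3 superkingdom
write_tiny_taxdump <- function(dir = tempfile("taxdump")) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tsuperkingdom\t|",
    "3\t|\t1\t|\tsuperkingdom\t|",
    "10\t|\t2\t|\tgenus\t|",
    "11\t|\t10\t|\tspecies\t|",
    "12\t|\t10\t|\tspecies\t|"
  ), file.path(dir, "nodes.dmp"))
  writeLines(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
    "3\t|\tArchaea\t|\t\t|\tscientific name\t|",
    "10\t|\tLeptospirillum\t|\t\t|\tscientific name\t|",
    "11\t|\tLeptospirillum rubarum\t|\t\t|\tscientific name\t|",
    "12\t|\tLeptospirillum ferrodiazotrophum\t|\t\t|\tscientific name\t|"
  ), file.path(dir, "names.dmp"))
  dir
}

tiny_db <- function() {
  d <- write_tiny_taxdump()
  load_taxonomy(file.path(d, "nodes.dmp"), file.path(d, "names.dmp"))
}

make_hit <- function(query = "q1", taxon = 11L, bit = 100, ev = 1e-20,
                     ident = 95) {
  data.frame(query_id = query, subject_id = sprintf("s%d", taxon),
             subject_taxon = as.integer(taxon), percent_identity = ident,
             e_value = ev, bit_score = bit, stringsAsFactors = FALSE)
}

# Random chart (tree + datasets + attributes + collapsed entries) for
# round-trip tests.
random_chart <- function(seed, max_nodes = 40L) {
  set.seed(seed)
  n_datasets <- sample(1:3, 1L)
  root <- random_tree(sample(3:max_nodes, 1L), n_datasets,
                      seed = seed + 1000L, integer_mag = FALSE)
  decorate <- function(n) {
    if (stats::runif(1) < 0.4) {
      n$attributes[["confidence"]] <- list(
        mean = round(stats::runif(n_datasets), 6),
        weight = round(stats::runif(n_datasets, 0, 20), 6))
    }
    if (stats::runif(1) < 0.2) {
      n$attributes[["note"]] <- "<a href='https://example.org'>link & notes</a>"
    }
    if (stats::runif(1) < 0.2) {
      n$collapsed <- list(list(name = "Absorbed rank", rank = "order",
                               taxon_id = sample.int(1e6, 1L)))
    }
    if (stats::runif(1) < 0.3) {
      n$rank <- sample(c("phylum", "genus", "species"), 1L)
      n$taxon_id <- sample.int(1e6, 1L)
    }
    n$children <- lapply(n$children, decorate)
    n
  }
  chart(decorate(root),
        dataset_names = sprintf("sample %d", seq_len(n_datasets)),
        attribute_defs = list(
          attribute_def("confidence", "Avg. confidence",
                        gradient = gradient_spec("confidence", domain = c(0, 1))),
          attribute_def("note", aggregation = "none")),
        max_depth = sample(c(Inf, 4, 6), 1L),
        collapse = sample(c(TRUE, FALSE), 1L))
}

# Parent path of a /-joined node path; NA at the root.
dirname_path <- function(p) {
  out <- sub("/[^/]*$", "", p)
  ifelse(grepl("/", p, fixed = TRUE), out, NA_character_)
}
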