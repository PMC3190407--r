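## Rank ladder cycled by depth when generating toy taxonomies.
RANK_LADDER <- c("no rank", "superkingdom", "phylum", "class", "order",
                 "family", "genus", "species")

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy NCBI-dialect taxonomy
#'
#' Builds a random acyclic taxonomy of `n_nodes` taxa: node 1 is the root
#' (its own parent), each later node attaches to a uniformly chosen earlier
#' node with fewer than `branching` children, and ranks cycle through a fixed
#' ladder by depth. Deterministic for a given seed. When `dir` is given,
#' `nodes.dmp` and `names.dmp` are written there in the dump dialect the
#' loader consumes.
#'
#' @param n_nodes Number of taxa (>= 1).
#' @param branching Maximum children per node.
#' @param seed RNG seed.
#' @param dir Optional output directory for the dump files.
#' @return A `taxonomy_db` (loaded back through [load_taxonomy()] when `dir`
#'   is given, so the files are verified on the way out).
#' @export
make_toy_taxonomy <- function(n_nodes, branching = 3L, seed = 1L, dir = NULL) {
  stopifnot(n_nodes >= 1L, branching >= 1L)
  with_seed(seed, {
    parent <- integer(n_nodes)
    depth <- integer(n_nodes)
    n_children <- integer(n_nodes)
    parent[1L] <- 1L
    depth[1L] <- 1L
    for (i in seq_len(n_nodes)[-1L]) {
      open <- which(n_children[seq_len(i - 1L)] < branching)
      p <- open[sample.int(length(open), 1L)]
      parent[i] <- p
      depth[i] <- depth[p] + 1L
      n_children[p] <- n_children[p] + 1L
    }
    ranks <- RANK_LADDER[(depth - 1L) %% length(RANK_LADDER) + 1L]
    names_ <- c("toy root", sprintf("Taxon %d", seq_len(n_nodes)[-1L]))[seq_len(n_nodes)]
    db <- structure(list(ids = seq_len(n_nodes), parent = parent, rank = ranks,
                         name = names_, root_id = 1L, merged = NULL),
                    class = "taxonomy_db")
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", db$ids, db$parent, db$rank),
                 file.path(dir, "nodes.dmp"))
      writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", db$ids, db$name),
                 file.path(dir, "names.dmp"))
      db <- load_taxonomy(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
    }
    db
  })
}

#' Generate synthetic BLAST hits with known answers
#'
#' For each query a true leaf taxon is drawn. With probability
#' `tie_fraction` the query instead hits two sibling leaves with exactly equal
#' top bit scores, so the expected assignment (at `score_factor = 1`) is the
#' siblings' lowest common ancestor; otherwise a single best hit points at the
#' true taxon. Decoy hits with strictly lower scores are added up to
#' `hits_per_query`. E-values are log-uniform on [1e-50, 1e-3] and identities
#' uniform on [70, 100]. A ground-truth sidecar records, per query, the true
#' taxon and the expected LCA assignment, so tests never re-derive
#' expectations by hand.
#'
#' @param db A `taxonomy_db` with at least two sibling leaves.
#' @param n_queries Number of queries.
#' @param hits_per_query Hits emitted per query.
#' @param tie_fraction Fraction of queries constructed as exact sibling ties.
#' @param seed RNG seed.
#' @param dir Output directory for `hits.tsv` and `truth.tsv`.
#' @return `list(hits_path, truth_path, taxon_map, truth)` where `truth` is a
#'   data frame with `query_id`, `true_taxon`, `expected_taxon`.
#' @export
make_synthetic_hits <- function(db, n_queries = 100L, hits_per_query = 3L,
                                tie_fraction = 0, seed = 1L,
                                dir = tempfile("hits")) {
  stopifnot(hits_per_query >= 1L, tie_fraction >= 0, tie_fraction <= 1)
  leaves <- setdiff(db$ids, db$parent)
  leaf_parents <- db$parent[match(leaves, db$ids)]
  sib_parents <- unique(leaf_parents[duplicated(leaf_parents)])
  if (tie_fraction > 0 && length(sib_parents) == 0L) {
    stop("make_synthetic_hits: taxonomy has no sibling leaf pair for ties")
  }
  with_seed(seed, {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    lines <- character(0)
    truth <- vector("list", n_queries)
    for (q in seq_len(n_queries)) {
      qid <- sprintf("q%04d", q)
      is_tie <- stats::runif(1) < tie_fraction
      if (is_tie) {
        p <- sib_parents[[sample.int(length(sib_parents), 1L)]]
        sibs <- leaves[leaf_parents == p]
        pair <- sibs[sample.int(length(sibs), 2L)]
        top_taxa <- pair
        true_taxon <- pair[[1L]]
        expected <- lca(db, pair)
      } else {
        true_taxon <- leaves[[sample.int(length(leaves), 1L)]]
        top_taxa <- true_taxon
        expected <- true_taxon
      }
      best_bit <- stats::runif(1, 180, 220)
      n_decoys <- max(0L, hits_per_query - length(top_taxa))
      decoy_taxa <- if (n_decoys > 0L) {
        db$ids[sample.int(length(db$ids), n_decoys, replace = TRUE)]
      } else integer(0)
      taxa <- c(top_taxa, decoy_taxa)
      bits <- c(rep(best_bit, length(top_taxa)),
                stats::runif(n_decoys, 40, best_bit * 0.8))
      ev <- 10^stats::runif(length(taxa), -50, -3)
      ident <- stats::runif(length(taxa), 70, 100)
      lines <- c(lines, sprintf(
        "%s\ts%d\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
        qid, taxa, ident, 100L, 2L, 0L, 1L, 100L, 1L, 100L, ev, bits))
      truth[[q]] <- data.frame(query_id = qid, true_taxon = true_taxon,
                               expected_taxon = expected,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    hits_path <- file.path(dir, "hits.tsv")
    truth_path <- file.path(dir, "truth.tsv")
    writeLines(c("# synthetic hits (12-column tabular dialect)", lines), hits_path)
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    taxon_map <- stats::setNames(db$ids, sprintf("s%d", db$ids))
    list(hits_path = hits_path, truth_path = truth_path,
         taxon_map = taxon_map, truth = truth)
  })
}

#' Generate a skewed abundance profile as a lineage text file
#'
#' Writes a lineage + magnitude file whose built chart reproduces the
#' requested top-level wedge fractions exactly: each named group receives
#' `fraction * total_magnitude` under the root, and any remainder is assigned
#' directly to the root (the unassigned remainder wedge).
#'
#' @param fractions Named numeric vector of top-level fractions, sum <= 1.
#' @param total_magnitude Total magnitude of the chart.
#' @param path Output file path.
#' @param root_name Root label.
#' @return `path`, invisibly.
#' @export
make_skewed_profile <- function(fractions, total_magnitude = 1000,
                                path = tempfile(fileext = ".tsv"),
                                root_name = "Root") {
  if (length(fractions) == 0L) stop("make_skewed_profile: empty fractions")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("make_skewed_profile: fractions must be named")
  }
  if (any(fractions < 0) || sum(fractions) > 1) {
    stop("make_skewed_profile: fractions must be non-negative and sum to <= 1")
  }
  lines <- sprintf("%s\t%s\t%s", fmt_num(fractions * total_magnitude),
                   root_name, names(fractions))
  rem <- total_magnitude - sum(fractions * total_magnitude)
  if (rem > 0) lines <- c(lines, sprintf("%s\t%s", fmt_num(rem), root_name))
  writeLines(lines, path)
  invisible(path)
}
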