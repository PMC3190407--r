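## E-values of 0.0 (BLAST underflow) are clamped here before taking log10.
EVALUE_FLOOR <- 1e-300

#' Keep the top-scoring hits of one query
#'
#' Retains the hits whose bit score is at least `score_factor` times the
#' query's maximum bit score, preserving input order. With the default factor
#' of 1 only exact ties with the best hit survive; smaller factors admit
#' near-optimal hits.
#'
#' @param hits Data frame of hits for a single query (see
#'   [read_blast_tabular()] for columns).
#' @param score_factor Fraction of the maximum bit score, in (0, 1].
#' @return The filtered data frame.
#' @export
select_top_hits <- function(hits, score_factor = 1) {
  if (NROW(hits) == 0L) stop("select_top_hits: empty hit list")
  if (!is.numeric(score_factor) || score_factor <= 0 || score_factor > 1) {
    stop("select_top_hits: score_factor must be in (0, 1]")
  }
  hits[hits$bit_score >= score_factor * max(hits$bit_score), , drop = FALSE]
}

#' Classify one query by lowest common ancestor
#'
#' Filters the query's hits with [select_top_hits()], resolves their subject
#' taxa against the taxonomy, and assigns the query to the lowest common
#' ancestor of the surviving taxa. The per-query attributes entering
#' downstream aggregation come from the single best-scoring hit (ties broken
#' by subject taxon id): `avg_log_evalue` is log10 of its e-value (zero
#' e-values clamped to 1e-300) and `identity` its percent identity.
#'
#' @param hits Data frame of hits for one query.
#' @param db A `taxonomy_db`.
#' @param score_factor Passed to [select_top_hits()].
#' @param strict If `TRUE`, a query whose subject taxa are all unresolvable is
#'   an error; otherwise it yields `NULL` (callers count and skip).
#' @return `list(query_id, taxon, magnitude = 1, attributes = list(...))`, or
#'   `NULL` when unresolvable in non-strict mode.
#' @export
classify_query <- function(hits, db, score_factor = 1, strict = FALSE) {
  top <- select_top_hits(hits, score_factor)
  taxa <- resolve_taxon(db, top$subject_taxon)
  ok <- !is.na(taxa)
  if (!any(ok)) {
    if (strict) {
      stop(sprintf("query '%s': no resolvable subject taxa", hits$query_id[[1L]]))
    }
    return(NULL)
  }
  top <- top[ok, , drop = FALSE]
  taxa <- taxa[ok]
  best <- top[order(-top$bit_score, top$subject_taxon), , drop = FALSE][1L, ]
  list(
    query_id = hits$query_id[[1L]],
    taxon = lca(db, taxa),
    magnitude = 1,
    attributes = list(
      avg_log_evalue = log10(max(best$e_value, EVALUE_FLOOR)),
      identity = best$percent_identity
    )
  )
}

#' Classify every query of a grouped hit table
#'
#' @param hit_groups Named list of per-query hit data frames, as returned by
#'   [read_blast_tabular()].
#' @param db A `taxonomy_db`.
#' @param score_factor Passed to [select_top_hits()].
#' @param strict Passed to [classify_query()].
#' @return `list(assignments = , skipped = )` where `assignments` is a list of
#'   per-query assignment records and `skipped` counts queries dropped for
#'   unresolvable taxa (also reported via `message()`).
#' @export
classify_hits <- function(hit_groups, db, score_factor = 1, strict = FALSE) {
  out <- vector("list", length(hit_groups))
  skipped <- 0L
  for (i in seq_along(hit_groups)) {
    a <- classify_query(hit_groups[[i]], db, score_factor, strict)
    if (is.null(a)) skipped <- skipped + 1L else out[[i]] <- a
  }
  if (skipped > 0L) {
    message(sprintf("classify_hits: skipped %d quer%s with no resolvable taxa",
                    skipped, if (skipped == 1L) "y" else "ies"))
  }
  list(assignments = Filter(Negate(is.null), out), skipped = skipped)
}

#' Attach per-sequence magnitudes to assignments
#'
#' Replaces each assignment's magnitude (default 1) with the mapped value when
#' the query id appears in `magnitudes`; unmapped queries keep their current
#' magnitude. Typical use: reads-per-contig weights from an ACE assembly via
#' [read_ace_magnitudes()].
#'
#' @param assignments List of assignment records.
#' @param magnitudes Named numeric vector, query id -> positive magnitude.
#' @return The updated assignment list.
#' @export
apply_magnitudes <- function(assignments, magnitudes) {
  if (length(magnitudes) == 0L) return(assignments)
  if (any(!is.finite(magnitudes)) || any(magnitudes <= 0)) {
    stop("apply_magnitudes: magnitudes must be positive and finite")
  }
  lapply(assignments, function(a) {
    m <- magnitudes[a$query_id]
    if (!is.na(m)) a$magnitude <- unname(m)
    a
  })
}

## Turn taxon-level assignments into lineage assignments for build_tree().
assignments_to_lineages <- function(assignments, db) {
  lapply(assignments, function(a) {
    lin <- lineage_names(db, a$taxon)
    list(lineage = lin$names, ranks = lin$ranks, taxon_ids = lin$ids,
         magnitude = a$magnitude, attributes = a$attributes)
  })
}
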