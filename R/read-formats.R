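#' Read BLAST tabular hits grouped by query
#'
#' Parses the 12-column tab-separated BLAST tabular dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bit score). Lines starting `#` are ignored. Subjects
#' are mapped to taxon ids with `taxon_map`; unmapped subjects get taxon `NA`
#' and are handled by the classification policy downstream.
#'
#' @param path Path to the hit file.
#' @param taxon_map Named integer vector, subject id -> taxon id, or `NULL` if
#'   the subject column already holds integer taxon ids.
#' @return Named list of data frames (one per query, input order preserved)
#'   with columns `query_id`, `subject_id`, `subject_taxon`,
#'   `percent_identity`, `e_value`, `bit_score`.
#' @export
read_blast_tabular <- function(path, taxon_map = NULL) {
  lines <- read_data_lines(path)
  keep <- !startsWith(lines$text, "#")
  text <- lines$text[keep]
  lineno <- lines$lineno[keep]
  if (length(text) == 0L) stop(sprintf("%s: no hit records", path))
  fields <- strsplit(text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop(sprintf("%s: line %d has %d columns, expected 12",
                 path, lineno[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("%s: line %d: non-numeric %s '%s'",
                   path, lineno[bad], what, m[bad, col]))
    }
    v
  }
  subject_id <- m[, 2L]
  subject_taxon <- if (is.null(taxon_map)) {
    suppressWarnings(as.integer(subject_id))
  } else {
    as.integer(unname(taxon_map[subject_id]))
  }
  hits <- data.frame(
    query_id = m[, 1L],
    subject_id = subject_id,
    subject_taxon = subject_taxon,
    percent_identity = num(3L, "percent identity"),
    e_value = num(11L, "e-value"),
    bit_score = num(12L, "bit score"),
    stringsAsFactors = FALSE
  )
  if (any(hits$e_value < 0)) stop(sprintf("%s: negative e-value", path))
  split(hits, factor(hits$query_id, levels = unique(hits$query_id)))
}

#' Read a generic lineage + magnitude text file
#'
#' Tab-separated, one classification per line: a numeric magnitude followed by
#' one column per lineage level, most general first. Trailing blank columns
#' are tolerated; repeated identical lineages are legal and accumulate when
#' the tree is built.
#'
#' @param path Path to the file.
#' @return List of `list(lineage = , magnitude = )` assignments for
#'   [build_tree()].
#' @export
read_text_lineage <- function(path) {
  lines <- read_data_lines(path)
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- drop_trailing_blanks(fields[[i]])
    mag <- suppressWarnings(as.numeric(f[[1L]]))
    if (is.na(mag)) {
      stop(sprintf("%s: line %d: non-numeric magnitude '%s'",
                   path, lines$lineno[i], f[[1L]]))
    }
    if (length(f) < 2L) {
      stop(sprintf("%s: line %d: magnitude without a lineage", path, lines$lineno[i]))
    }
    out[[i]] <- list(lineage = f[-1L], magnitude = mag)
  }
  out
}

#' Read RDP-Classifier-style fixed-rank assignments
#'
#' Tab-separated rows: a query id followed by repeating (name, rank,
#' confidence) triplets, most general rank first, confidences in [0, 1]. A
#' shorter row simply yields a shorter lineage.
#'
#' @param path Path to the file.
#' @return List of assignments carrying a per-level `confidence` lineage
#'   attribute, ready for [build_tree()].
#' @export
read_rdp <- function(path) {
  lines <- read_data_lines(path)
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- drop_trailing_blanks(fields[[i]])
    if (length(f) < 4L || (length(f) - 1L) %% 3L != 0L) {
      stop(sprintf("%s: line %d: expected id plus (name, rank, confidence) triplets",
                   path, lines$lineno[i]))
    }
    tri <- matrix(f[-1L], nrow = 3L)
    conf <- suppressWarnings(as.numeric(tri[3L, ]))
    if (anyNA(conf) || any(conf < 0) || any(conf > 1)) {
      stop(sprintf("%s: line %d: confidence outside [0, 1]", path, lines$lineno[i]))
    }
    out[[i]] <- list(
      query_id = f[[1L]],
      lineage = tri[1L, ],
      ranks = tri[2L, ],
      magnitude = 1,
      lineage_attributes = list(confidence = conf)
    )
  }
  out
}

#' Read PhymmBL-style per-read rank predictions
#'
#' Header-led tab-separated table: the first column is the read id, then pairs
#' of columns `<rank>` and `<rank>_conf` from the most general to the most
#' specific rank. A read's lineage is truncated at its first unnamed rank.
#'
#' @param path Path to the file.
#' @return List of assignments with a per-level `confidence` attribute, as
#'   [read_rdp()].
#' @export
read_phymmbl <- function(path) {
  lines <- read_data_lines(path)
  if (nrow(lines) < 1L) stop(sprintf("%s: missing header line", path))
  header <- strsplit(lines$text[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || (length(header) - 1L) %% 2L != 0L ||
      !all(grepl("_conf$", header[seq(3L, length(header), by = 2L)]))) {
    stop(sprintf("%s: malformed header; expected id then <rank>, <rank>_conf pairs",
                 path))
  }
  rank_names <- header[seq(2L, length(header), by = 2L)]
  body <- lines[-1L, , drop = FALSE]
  out <- vector("list", nrow(body))
  for (i in seq_len(nrow(body))) {
    f <- strsplit(body$text[[i]], "\t", fixed = TRUE)[[1L]]
    length(f) <- length(header)          # pad missing trailing columns
    f[is.na(f)] <- ""
    nm <- f[seq(2L, length(header), by = 2L)]
    cf <- suppressWarnings(as.numeric(f[seq(3L, length(header), by = 2L)]))
    named <- nzchar(nm)
    k <- if (any(!named)) which(!named)[1L] - 1L else length(nm)
    if (k == 0L) {
      stop(sprintf("%s: line %d: no named ranks", path, body$lineno[i]))
    }
    conf <- cf[seq_len(k)]
    if (anyNA(conf) || any(conf < 0) || any(conf > 1)) {
      stop(sprintf("%s: line %d: confidence outside [0, 1]", path, body$lineno[i]))
    }
    out[[i]] <- list(
      query_id = f[[1L]],
      lineage = nm[seq_len(k)],
      ranks = rank_names[seq_len(k)],
      magnitude = 1,
      lineage_attributes = list(confidence = conf)
    )
  }
  out
}

#' Read reads-per-contig magnitudes from an ACE assembly
#'
#' Scans contig headers of the form `CO <name> <bases> <nreads> ...` and maps
#' each contig to its declared read count. If an `AS <ncontigs> <nreads>`
#' total line disagrees with the parsed contigs a warning is raised, not an
#' error.
#'
#' @param path Path to the ACE file.
#' @return Named numeric vector, contig id -> read count, suitable for
#'   [apply_magnitudes()].
#' @export
read_ace_magnitudes <- function(path) {
  lines <- read_data_lines(path)
  ids <- character(0)
  counts <- numeric(0)
  as_contigs <- NA_real_
  as_reads <- NA_real_
  total_reads <- 0
  for (i in seq_len(nrow(lines))) {
    f <- strsplit(lines$text[[i]], " +")[[1L]]
    if (f[[1L]] == "AS" && length(f) >= 3L) {
      as_contigs <- suppressWarnings(as.numeric(f[[2L]]))
      as_reads <- suppressWarnings(as.numeric(f[[3L]]))
    } else if (f[[1L]] == "CO") {
      if (length(f) < 4L) {
        stop(sprintf("%s: line %d: malformed CO header", path, lines$lineno[i]))
      }
      n <- suppressWarnings(as.numeric(f[[4L]]))
      if (is.na(n)) {
        stop(sprintf("%s: line %d: non-numeric read count '%s'",
                     path, lines$lineno[i], f[[4L]]))
      }
      if (f[[2L]] %in% ids) {
        stop(sprintf("%s: line %d: duplicate contig name '%s'",
                     path, lines$lineno[i], f[[2L]]))
      }
      ids <- c(ids, f[[2L]])
      counts <- c(counts, n)
      total_reads <- total_reads + n
    }
  }
  if (!is.na(as_contigs) &&
      (as_contigs != length(ids) || (!is.na(as_reads) && as_reads != total_reads))) {
    warning(sprintf("%s: AS totals (%g contigs, %g reads) disagree with parsed contigs (%d, %g)",
                    path, as_contigs, as_reads, length(ids), total_reads))
  }
  stats::setNames(counts, ids)
}

## Non-empty lines with their original line numbers.
read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(raw)
  data.frame(text = raw[keep], lineno = which(keep), stringsAsFactors = FALSE)
}

drop_trailing_blanks <- function(f) {
  while (length(f) > 0L && !nzchar(f[[length(f)]])) f <- f[-length(f)]
  f
}
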