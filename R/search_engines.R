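# Pluggable homology-search backends. The ISS orchestration only needs the
# engine contract: given a query (possibly a sub-region with its full-sequence
# offset), a database, an E-value cutoff and a hit cap, return search_hits in
# full-sequence coordinates, sorted by ascending E-value, all within the
# cutoff. Two backends ship: a self-contained Smith-Waterman scan and an
# adapter for externally produced BLAST-style tabular reports.

# Karlin-Altschul parameters for gapped BLOSUM62 / open 11 / extend 1.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' E-value and bit score from a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the published gapped
#' BLOSUM62/11,1 constants `lambda = 0.267`, `K = 0.041`. This is a fixed,
#' roughly calibrated conversion: it is monotone decreasing in the score,
#' which is all the path-ranking logic relies on.
#'
#' @param score Raw alignment score.
#' @param m,n Query and subject lengths.
#' @return `evalue_from_score`: the E-value; `bitscore_from_score`: the bit
#'   score `(lambda * S - ln K) / ln 2`.
#' @export
evalue_from_score <- function(score, m, n) {
  .KA_K * m * n * exp(-.KA_LAMBDA * score)
}

#' @rdname evalue_from_score
#' @export
bitscore_from_score <- function(score, m = NULL, n = NULL) {
  (.KA_LAMBDA * score - log(.KA_K)) / log(2)
}

# Sort hits by ascending evalue, tie-broken by descending bitscore then
# subject id; truncate to max_hits.
finalize_hits <- function(hits, max_hits) {
  if (!length(hits)) return(list())
  ev <- vapply(hits, function(h) h$evalue, 0)
  bs <- vapply(hits, function(h) ifelse(is.na(h$bitscore), 0, h$bitscore), 0)
  sid <- vapply(hits, function(h) h$subject_id, "")
  hits <- hits[order(ev, -bs, sid)]
  hits[seq_len(min(length(hits), max_hits))]
}

#' Scan a database with Smith-Waterman
#'
#' The built-in search backend: aligns the query (or a query sub-region)
#' against every database record with [smith_waterman()] and converts scores
#' to E-values via [evalue_from_score()]. Hit regions are the locally aligned
#' regions lifted to full-sequence coordinates. Self-hits (subject id equal
#' to the query id) are excluded.
#'
#' @param query A [seq_record()].
#' @param db A [seq_database()].
#' @param scheme A [scoring_scheme()].
#' @param evalue_cutoff Positive E-value cutoff; hits above it are dropped.
#' @param max_hits Cap on the number of returned hits.
#' @param layer Search layer recorded on the hits (0 = first search from the
#'   original query).
#' @param query_region Optional [region()] on the query: only this sub-region
#'   is used as the search query, and reported query coordinates are lifted
#'   back to the full sequence.
#' @return List of [search_hit()] sorted by ascending E-value.
#' @export
scan_search <- function(query, db, scheme = scoring_scheme(),
                        evalue_cutoff = 10, max_hits = 100L, layer = 0L,
                        query_region = NULL) {
  stopifnot(inherits(query, "seq_record"), inherits(db, "seq_database"))
  if (!is.numeric(evalue_cutoff) || evalue_cutoff <= 0)
    stop("evalue_cutoff must be positive")
  if (is.null(query_region)) {
    qsub <- query; qoff <- 0L
  } else {
    qsub <- sub_record(query, query_region$start, query_region$end)
    qoff <- query_region$start
  }
  hits <- list()
  for (rec in db$records) {
    if (identical(rec$id, query$id)) next
    r <- smith_waterman(qsub, rec, scheme)
    if (r$score <= 0) next
    ev <- evalue_from_score(r$score, qsub$length, rec$length)
    if (ev > evalue_cutoff) next
    hits[[length(hits) + 1L]] <- search_hit(
      query_id = query$id, subject_id = rec$id,
      query_region = region(query$id,
                            r$query_region$start + qoff,
                            r$query_region$end + qoff, query$length),
      subject_region = r$subject_region,
      evalue = ev,
      bitscore = bitscore_from_score(r$score),
      layer = layer)
  }
  finalize_hits(hits, max_hits)
}

#' Parse BLAST-style tabular hits
#'
#' Reads the 8-column tabular dialect `qseqid sseqid evalue bitscore qstart
#' qend sstart send` (1-based inclusive coordinates, as produced by BLAST+
#' with a custom `-outfmt` directive) and converts coordinates to the
#' package's 0-based half-open convention. Multiple rows for one
#' (query, subject) pair are collapsed to the row with the smallest E-value;
#' output order follows the retained rows' file order.
#'
#' @param text Path to a tabular report, or a character vector of its lines.
#' @param layer Search layer recorded on the hits.
#' @return List of [search_hit()].
#' @export
parse_tabular_hits <- function(text, layer = 0L) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*#", lines)]
  keep <- nzchar(trimws(lines))
  hits <- list(); keys <- character()
  for (ln in seq_along(lines)) {
    if (!keep[ln]) next
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(f) != 8L)
      stop("parse error at line ", ln, ": expected 8 columns, got ", length(f))
    ev <- suppressWarnings(as.numeric(f[3L]))
    bs <- suppressWarnings(as.numeric(f[4L]))
    co <- suppressWarnings(as.integer(f[5:8]))
    if (is.na(ev) || is.na(bs) || anyNA(co))
      stop("parse error at line ", ln, ": non-numeric field")
    if (any(co < 1L) || co[1L] > co[2L] || co[3L] > co[4L])
      stop("parse error at line ", ln, ": invalid 1-based coordinates")
    h <- search_hit(f[1L], f[2L],
                    region(f[1L], co[1L] - 1L, co[2L]),
                    region(f[2L], co[3L] - 1L, co[4L]),
                    evalue = ev, bitscore = bs, layer = layer)
    key <- paste0(f[1L], "\r", f[2L])
    at <- match(key, keys)
    if (is.na(at)) {
      hits[[length(hits) + 1L]] <- h
      keys[length(keys) + 1L] <- key
    } else if (ev < hits[[at]]$evalue) {
      hits[[at]] <- h
    }
  }
  hits
}

#' Search engine constructors
#'
#' An engine is a function `(query, query_region, db, evalue_cutoff,
#' max_hits, layer) -> list of search_hit` satisfying the engine contract
#' (ascending E-values, all within the cutoff, at most `max_hits`).
#' `scan_engine()` wraps [scan_search()]; `tabular_engine()` serves
#' pre-parsed hits from an external tool's report, filtered by query id and
#' cutoff (the database argument is used only for context).
#'
#' @param scheme A [scoring_scheme()] for `scan_engine`.
#' @param hits List of [search_hit()] (e.g. from [parse_tabular_hits()]) for
#'   `tabular_engine`.
#' @return A function implementing the engine contract.
#' @export
scan_engine <- function(scheme = scoring_scheme()) {
  function(query, query_region, db, evalue_cutoff, max_hits, layer) {
    scan_search(query, db, scheme, evalue_cutoff, max_hits, layer,
                query_region = query_region)
  }
}

#' @rdname scan_engine
#' @export
tabular_engine <- function(hits) {
  force(hits)
  function(query, query_region, db, evalue_cutoff, max_hits, layer) {
    if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive")
    sel <- Filter(function(h) {
      identical(h$query_id, query$id) && h$evalue <= evalue_cutoff &&
        !identical(h$subject_id, query$id) &&
        h$subject_id %in% names(db$records)
    }, hits)
    sel <- lapply(sel, function(h) { h$layer <- as.integer(layer); h })
    finalize_hits(sel, max_hits)
  }
}
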