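# Layered intermediate sequence search (ISS). Hits of one search round become
# queries of the next: the extended sub-region of each hit — not the whole
# detected sequence — is re-queried, which limits the false positives that
# unrelated domains of multi-domain intermediates would otherwise drag in.
# Final hits are ranked by the sum of E-values along the best path.

#' ISS configuration
#'
#' @param n_intermediate_layers Number of intermediate search rounds (>= 0;
#'   1 and 2 are the typical settings).
#' @param extension_lengths One non-negative integer per search performed
#'   (`n_intermediate_layers + 1` entries): the number of residues by which a
#'   hit region is widened on each side. Defaults to 5 for intermediate
#'   layers and 20 for the final layer.
#' @param evalue_cutoffs One positive E-value cutoff per search. Defaults to
#'   1e-3 for intermediate layers and 10 for the final layer.
#' @param max_hits_per_layer One positive hit cap per search (default 100).
#' @param scheme A [scoring_scheme()] used by the built-in engine and by
#'   alignment generation.
#' @param use_subregions If `FALSE`, whole intermediate sequences are
#'   re-queried instead of extended hit sub-regions. Only intended for
#'   ablation experiments; the default `TRUE` is the method.
#' @return An object of class `iss_config`.
#' @export
iss_config <- function(n_intermediate_layers = 2L,
                       extension_lengths = NULL,
                       evalue_cutoffs = NULL,
                       max_hits_per_layer = NULL,
                       scheme = scoring_scheme(),
                       use_subregions = TRUE) {
  k <- as.integer(n_intermediate_layers)
  if (is.na(k) || k < 0L) stop("n_intermediate_layers must be >= 0")
  if (is.null(extension_lengths)) extension_lengths <- c(rep(5L, k), 20L)
  if (is.null(evalue_cutoffs)) evalue_cutoffs <- c(rep(1e-3, k), 10)
  if (is.null(max_hits_per_layer)) max_hits_per_layer <- rep(100L, k + 1L)
  extension_lengths <- as.integer(extension_lengths)
  max_hits_per_layer <- as.integer(max_hits_per_layer)
  if (length(extension_lengths) != k + 1L || any(extension_lengths < 0L))
    stop("extension_lengths needs one nonnegative entry per search (", k + 1L, ")")
  if (length(evalue_cutoffs) != k + 1L || any(evalue_cutoffs <= 0))
    stop("evalue_cutoffs needs one positive entry per search (", k + 1L, ")")
  if (length(max_hits_per_layer) != k + 1L || any(max_hits_per_layer < 1L))
    stop("max_hits_per_layer needs one positive entry per search (", k + 1L, ")")
  structure(list(n_intermediate_layers = k,
                 extension_lengths = extension_lengths,
                 evalue_cutoffs = evalue_cutoffs,
                 max_hits_per_layer = max_hits_per_layer,
                 scheme = scheme,
                 use_subregions = isTRUE(use_subregions)),
            class = "iss_config")
}

#' Extend a hit region
#'
#' Widens a region by `ext` residues on each side, clamped to the sequence
#' boundaries.
#'
#' @param r A [region()].
#' @param ext Non-negative extension length.
#' @param seq_length Length of the referenced sequence.
#' @return The extended [region()].
#' @examples
#' extend_region(region("s", 10, 20), 5, 100)  # [5, 25)
#' @export
extend_region <- function(r, ext, seq_length) {
  stopifnot(inherits(r, "region"), ext >= 0, r$end <= seq_length)
  region(r$sequence_id, max(0L, r$start - as.integer(ext)),
         min(as.integer(seq_length), r$end + as.integer(ext)), seq_length)
}

#' Intermediate sequence search
#'
#' Runs the layered search: the query is searched against the first
#' intermediate database; each hit's extended sub-region is re-queried
#' against the next database; the last search always targets the final
#' (structural) database. Paths are cycle-free — no sequence id appears twice
#' along one path. Direct (0-intermediate) hits of the query against the
#' final database are always merged into the candidate set, so ISS never
#' loses what a plain search finds.
#'
#' @param query A [seq_record()].
#' @param intermediate_dbs List of [seq_database()], one per intermediate
#'   layer (may be empty for a direct search).
#' @param final_db The final [seq_database()].
#' @param cfg An [iss_config()]; `cfg$n_intermediate_layers` must equal
#'   `length(intermediate_dbs)`.
#' @param engine A search engine function (see [scan_engine()]); defaults to
#'   the built-in Smith-Waterman scan with `cfg$scheme`.
#' @return List of [search_path()] objects ending in final-database subjects.
#' @export
iss_search <- function(query, intermediate_dbs, final_db, cfg = iss_config(),
                       engine = NULL) {
  stopifnot(inherits(query, "seq_record"), inherits(final_db, "seq_database"))
  k <- cfg$n_intermediate_layers
  if (length(intermediate_dbs) != k)
    stop("need exactly ", k, " intermediate database(s), got ",
         length(intermediate_dbs))
  if (is.null(engine)) engine <- scan_engine(cfg$scheme)

  search_layer <- function(fr, db, s) {
    # s is the 1-based index of the search (layer s - 1)
    tryCatch(
      engine(fr$rec, fr$reg, db, cfg$evalue_cutoffs[s],
             cfg$max_hits_per_layer[s], s - 1L),
      error = function(e)
        stop("search engine failed at layer ", s - 1L, ": ",
             conditionMessage(e)))
  }

  frontier <- list(list(hits = list(), rec = query, reg = NULL,
                        seen = query$id))
  for (s in seq_len(k)) {
    db <- intermediate_dbs[[s]]
    nxt <- list()
    for (fr in frontier) {
      for (h in search_layer(fr, db, s)) {
        if (h$subject_id %in% fr$seen) next
        sub <- db$records[[h$subject_id]]
        reg <- if (cfg$use_subregions)
          extend_region(h$subject_region, cfg$extension_lengths[s], sub$length)
        else NULL
        nxt[[length(nxt) + 1L]] <- list(
          hits = c(fr$hits, list(h)), rec = sub, reg = reg,
          seen = c(fr$seen, h$subject_id))
      }
    }
    frontier <- nxt
  }

  paths <- list()
  for (fr in frontier) {
    for (h in search_layer(fr, final_db, k + 1L)) {
      if (h$subject_id %in% fr$seen) next
      paths[[length(paths) + 1L]] <- search_path(c(fr$hits, list(h)))
    }
  }
  if (k > 0L) {
    direct <- engine(query, NULL, final_db, cfg$evalue_cutoffs[k + 1L],
                     cfg$max_hits_per_layer[k + 1L], 0L)
    for (h in direct)
      paths[[length(paths) + 1L]] <- search_path(list(h))
  }
  paths
}

#' Rank final hits by best path score
#'
#' Groups paths by their final subject, keeps per subject the path with the
#' smallest sum of E-values (ties: shorter path first, then the
#' lexicographically smallest id chain), and ranks subjects by ascending best
#' score (ties: shorter best path, then subject id).
#'
#' @param paths List of [search_path()] (e.g. from [iss_search()]).
#' @return List of `ranked_hit` objects with fields `subject_id`,
#'   `best_path`, `score` and `rank`. Empty input yields an empty list.
#' @export
rank_hits <- function(paths) {
  if (!length(paths)) return(list())
  subj <- vapply(paths, function(p) p$hits[[length(p$hits)]]$subject_id, "")
  score <- vapply(paths, function(p) p$path_score, 0)
  plen <- vapply(paths, function(p) length(p$hits), 0L)
  pkey <- vapply(paths, function(p) paste(path_ids(p), collapse = ","), "")
  best <- integer()
  for (id in unique(subj)) {
    ix <- which(subj == id)
    ix <- ix[order(score[ix], plen[ix], pkey[ix])]
    best <- c(best, ix[1L])
  }
  best <- best[order(score[best], plen[best], subj[best])]
  out <- vector("list", length(best))
  for (r in seq_along(best)) {
    ix <- best[r]
    out[[r]] <- structure(list(subject_id = subj[ix], best_path = paths[[ix]],
                               score = score[ix], rank = r),
                          class = "ranked_hit")
  }
  out
}

#' Ranked hits as a data frame
#'
#' Flattens [rank_hits()] output into the tab-separated interchange format
#' used between the `search` and `align` stages: one row per ranked subject
#' with the id chain, per-edge E-values and per-edge regions.
#'
#' @param ranked List of `ranked_hit` objects.
#' @return A data.frame with columns `rank`, `subject_id`, `path_score`,
#'   `path`, `evalues`, `regions`.
#' @export
ranked_hits_table <- function(ranked) {
  if (!length(ranked)) {
    return(data.frame(rank = integer(), subject_id = character(),
                      path_score = numeric(), path = character(),
                      evalues = character(), regions = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(ranked, function(rh) {
    p <- rh$best_path
    ev <- vapply(p$hits, function(h) format(h$evalue, digits = 8), "")
    rg <- vapply(p$hits, function(h)
      sprintf("%d:%d>%d:%d", h$query_region$start, h$query_region$end,
              h$subject_region$start, h$subject_region$end), "")
    data.frame(rank = rh$rank, subject_id = rh$subject_id,
               path_score = rh$score,
               path = paste(path_ids(p), collapse = ","),
               evalues = paste(ev, collapse = ","),
               regions = paste(rg, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Rebuild a search_path from one row of the interchange table.
path_from_table_row <- function(row) {
  ids <- strsplit(row$path, ",", fixed = TRUE)[[1L]]
  ev <- as.numeric(strsplit(row$evalues, ",", fixed = TRUE)[[1L]])
  rg <- strsplit(row$regions, ";", fixed = TRUE)[[1L]]
  hits <- vector("list", length(ev))
  for (e in seq_along(ev)) {
    co <- as.integer(strsplit(rg[e], "[:>]")[[1L]])
    hits[[e]] <- search_hit(ids[e], ids[e + 1L],
                            region(ids[e], co[1L], co[2L]),
                            region(ids[e + 1L], co[3L], co[4L]),
                            evalue = ev[e], layer = e - 1L)
  }
  search_path(hits)
}
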