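# Alignment generation through intermediates. Per path edge a Smith-Waterman
# alignment is computed between the (extended) sub-sequences actually used in
# the search; the query-template correspondence is the composition of the
# per-edge residue maps, so every per-edge matched pair that survives
# composition appears unchanged in the output — no dynamic-programming
# re-alignment of anchored residues takes place during merging.

#' Compose two residue maps
#'
#' `pairs = {(i, k) : (i, j) in m1 and (j, k) in m2}`. Monotonicity of the
#' result is guaranteed by monotonicity of the inputs. `m1`'s target must be
#' `m2`'s source.
#'
#' @param m1,m2 [residue_map()] objects with `m1$target_id == m2$source_id`.
#' @return The composed [residue_map()] from `m1$source_id` to
#'   `m2$target_id`.
#' @examples
#' m1 <- residue_map("a", "b", c(0, 1, 4), c(2, 3, 5))
#' m2 <- residue_map("b", "c", c(2, 5), c(0, 1))
#' compose_maps(m1, m2)  # pairs (0,0), (4,1)
#' @export
compose_maps <- function(m1, m2) {
  stopifnot(inherits(m1, "residue_map"), inherits(m2, "residue_map"))
  if (!identical(m1$target_id, m2$source_id))
    stop("composition error: map ids do not chain (",
         m1$target_id, " vs ", m2$source_id, ")")
  at <- match(m1$j, m2$i)
  keep <- !is.na(at)
  residue_map(m1$source_id, m2$target_id, m1$i[keep], m2$j[at[keep]])
}

# Identity residue map over given 0-based positions.
identity_map <- function(id_a, id_b, positions) {
  residue_map(id_a, id_b, positions, positions)
}

#' Pairwise alignment realizing a residue map
#'
#' Emits an alignment whose matched columns are exactly the map's pairs.
#' Unmatched residues between consecutive anchors appear as residue-vs-gap
#' columns, query insertions before template insertions; sequence outside the
#' first/last anchor is trimmed (local alignment semantics).
#'
#' @param map A [residue_map()].
#' @param rec_a,rec_b The full [seq_record()] objects the map refers to.
#' @param scheme Optional [scoring_scheme()] used to score the result.
#' @return A [pairwise_alignment()]; an empty map yields an empty alignment.
#' @export
alignment_from_map <- function(map, rec_a, rec_b, scheme = NULL) {
  if (map_size(map) == 0L) return(empty_alignment(rec_a$id, rec_b$id))
  ca <- strsplit(rec_a$residues, "")[[1L]]
  cb <- strsplit(rec_b$residues, "")[[1L]]
  if (max(map$i) >= rec_a$length || max(map$j) >= rec_b$length)
    stop("map indices exceed sequence lengths")
  ra <- character(); rb <- character()
  for (k in seq_along(map$i)) {
    if (k > 1L) {
      if (map$i[k] - map$i[k - 1L] > 1L) {
        gi <- (map$i[k - 1L] + 1L):(map$i[k] - 1L)
        ra <- c(ra, ca[gi + 1L]); rb <- c(rb, rep("-", length(gi)))
      }
      if (map$j[k] - map$j[k - 1L] > 1L) {
        gj <- (map$j[k - 1L] + 1L):(map$j[k] - 1L)
        ra <- c(ra, rep("-", length(gj))); rb <- c(rb, cb[gj + 1L])
      }
    }
    ra <- c(ra, ca[map$i[k] + 1L]); rb <- c(rb, cb[map$j[k] + 1L])
  }
  aln <- pairwise_alignment(map$source_id, map$target_id,
                            map$i[1L], map$j[1L],
                            paste(ra, collapse = ""), paste(rb, collapse = ""))
  aln$score <- if (is.null(scheme)) NA_real_ else alignment_score(aln, scheme)
  aln
}

# --- merged multi-row alignment ------------------------------------------

# Internal representation during merging: an integer matrix, one row per
# sequence, entries = 0-based residue indices or NA for gaps.

aln_to_index_matrix <- function(aln) {
  ra <- strsplit(aln$a_row, "")[[1L]]
  rb <- strsplit(aln$b_row, "")[[1L]]
  ia <- ifelse(ra != "-", cumsum(ra != "-") - 1L + aln$a_start, NA_integer_)
  ib <- ifelse(rb != "-", cumsum(rb != "-") - 1L + aln$b_start, NA_integer_)
  rbind(ia, ib)
}

# Merge an edge alignment (2-row index matrix whose first row is over the
# same sequence as M's last row) into the growing stack M, synchronizing on
# the shared sequence's residue indices. Both inputs' column pairings are
# preserved exactly.
merge_on_common_row <- function(M, E2) {
  nr <- nrow(M); cM <- ncol(M); cE <- ncol(E2)
  out <- matrix(NA_integer_, nrow = nr + 1L, ncol = cM + cE)
  i <- 1L; j <- 1L; o <- 0L
  while (i <= cM || j <= cE) {
    o <- o + 1L
    mi <- if (i <= cM) M[nr, i] else NA_integer_
    ej <- if (j <= cE) E2[1L, j] else NA_integer_
    if (i <= cM && is.na(mi)) {
      out[1:nr, o] <- M[, i]; i <- i + 1L
    } else if (j <= cE && is.na(ej)) {
      out[nr + 1L, o] <- E2[2L, j]; j <- j + 1L
    } else if (i > cM) {
      out[nr, o] <- E2[1L, j]; out[nr + 1L, o] <- E2[2L, j]; j <- j + 1L
    } else if (j > cE) {
      out[1:nr, o] <- M[, i]; i <- i + 1L
    } else if (mi == ej) {
      out[1:nr, o] <- M[, i]; out[nr + 1L, o] <- E2[2L, j]
      i <- i + 1L; j <- j + 1L
    } else if (mi < ej) {
      out[1:nr, o] <- M[, i]; i <- i + 1L
    } else {
      out[nr, o] <- E2[1L, j]; out[nr + 1L, o] <- E2[2L, j]; j <- j + 1L
    }
  }
  out[, seq_len(o), drop = FALSE]
}

# Render an index matrix into a merged_alignment given the sequences.
render_merged <- function(M, ids, records) {
  rows <- character(nrow(M))
  for (r in seq_len(nrow(M))) {
    ch <- strsplit(records[[ids[r]]]$residues, "")[[1L]]
    rows[r] <- paste(ifelse(is.na(M[r, ]), "-", ch[M[r, ] + 1L]),
                     collapse = "")
  }
  structure(list(ids = ids, rows = rows, n_columns = ncol(M)),
            class = "merged_alignment")
}

#' @export
print.merged_alignment <- function(x, ...) {
  cat(sprintf("<merged_alignment: %d rows x %d columns (%s)>\n",
              length(x$ids), x$n_columns, paste(x$ids, collapse = ", ")))
  invisible(x)
}

resolve_records <- function(sequences) {
  if (inherits(sequences, "seq_database")) sequences$records else sequences
}

# Extension length for edge e of an E-edge path under cfg: the last edge of a
# path always uses the final-layer extension; earlier edges use their
# intermediate-layer value.
ext_for_edge <- function(cfg, e, n_edges) {
  ex <- cfg$extension_lengths
  if (e == n_edges) ex[length(ex)] else ex[e]
}

#' Query-template alignment from a search path
#'
#' For each edge of the path, Smith-Waterman is run between the sub-sequences
#' that the search actually used: the whole query for the first edge,
#' otherwise the previous hit's extended subject sub-region, against the
#' current hit's extended subject sub-region (the final edge uses the final
#' extension length). Each edge alignment is lifted to full-sequence
#' coordinates, the query-template residue map is the left-to-right
#' composition over all edges, and the merged stack threads every path
#' sequence so that each edge's pairwise alignment is preserved column for
#' column.
#'
#' @param path A [search_path()].
#' @param sequences A [seq_database()] or named list of [seq_record()]
#'   resolving every id on the path.
#' @param cfg An [iss_config()] supplying per-layer extension lengths and the
#'   scoring scheme.
#' @return A list with `pairwise` (the split-out query-template
#'   [pairwise_alignment()]; empty if the composed map is empty),
#'   `merged` (a `merged_alignment` over all path sequences, `NULL` when the
#'   composed map is empty), and `edge_alignments` (full-coordinate per-edge
#'   alignments).
#' @export
chain_to_alignment <- function(path, sequences, cfg = iss_config()) {
  stopifnot(inherits(path, "search_path"))
  records <- resolve_records(sequences)
  ids <- path_ids(path)
  missing <- setdiff(ids, names(records))
  if (length(missing))
    stop("unresolvable sequence id(s): ", paste(missing, collapse = ", "))
  nE <- length(path$hits)
  qrec <- records[[ids[1L]]]
  trec <- records[[ids[nE + 1L]]]

  edge_alns <- vector("list", nE)
  edge_maps <- vector("list", nE)
  prev_reg <- NULL
  for (e in seq_len(nE)) {
    h <- path$hits[[e]]
    arec <- records[[h$query_id]]
    brec <- records[[h$subject_id]]
    areg <- if (e == 1L || !cfg$use_subregions)
      region(arec$id, 0L, arec$length) else prev_reg
    breg <- extend_region(h$subject_region, ext_for_edge(cfg, e, nE),
                          brec$length)
    r <- smith_waterman(sub_record(arec, areg$start, areg$end),
                        sub_record(brec, breg$start, breg$end),
                        cfg$scheme)
    if (r$score <= 0) {
      return(list(pairwise = empty_alignment(qrec$id, trec$id),
                  merged = NULL, edge_alignments = edge_alns))
    }
    aln <- r$alignment
    aln$a_start <- aln$a_start + areg$start
    aln$b_start <- aln$b_start + breg$start
    edge_alns[[e]] <- aln
    edge_maps[[e]] <- residue_map_from_alignment(aln, 0L, 0L,
                                                 arec$length, brec$length)
    prev_reg <- if (cfg$use_subregions)
      extend_region(h$subject_region, ext_for_edge(cfg, e, nE + 1L),
                    brec$length) else NULL
  }
  composed <- Reduce(compose_maps, edge_maps)
  if (map_size(composed) == 0L) {
    return(list(pairwise = empty_alignment(qrec$id, trec$id),
                merged = NULL, edge_alignments = edge_alns))
  }
  M <- aln_to_index_matrix(edge_alns[[1L]])
  if (nE > 1L) {
    for (e in 2L:nE) M <- merge_on_common_row(M, aln_to_index_matrix(edge_alns[[e]]))
  }
  list(pairwise = alignment_from_map(composed, qrec, trec, cfg$scheme),
       merged = render_merged(M, ids, records),
       edge_alignments = edge_alns)
}

#' Select between intermediate-derived and direct alignment
#'
#' The intermediate route occasionally produces an obviously wrong alignment
#' (e.g. after a large register shift in an intermediate hit); such cases are
#' detectable by their short aligned region. The alignment with the larger
#' matched-column count is therefore selected; ties go to the
#' intermediate-derived alignment, which carries the remote-homology evidence
#' at equal coverage.
#'
#' @param via_intermediates,direct [pairwise_alignment()] objects for the
#'   same query-template pair.
#' @return A list with `alignment` (the chosen one) and `provenance`
#'   (`"intermediate"` or `"direct"`).
#' @export
select_alignment <- function(via_intermediates, direct) {
  li <- aligned_region_length(via_intermediates)
  ld <- aligned_region_length(direct)
  if (li >= ld)
    list(alignment = via_intermediates, provenance = "intermediate")
  else
    list(alignment = direct, provenance = "direct")
}

#' Full alignment generation for one template
#'
#' Convenience wrapper tying the pieces together: builds the
#' intermediate-derived alignment from the path ([chain_to_alignment()]),
#' computes the direct Smith-Waterman alignment of query and template, and
#' applies the longer-aligned-region selection rule.
#'
#' @inheritParams chain_to_alignment
#' @return A list with `alignment`, `provenance`, `merged`, `via` and
#'   `direct`.
#' @export
generate_alignment <- function(path, sequences, cfg = iss_config()) {
  records <- resolve_records(sequences)
  ids <- path_ids(path)
  via <- chain_to_alignment(path, records, cfg)
  qrec <- records[[ids[1L]]]
  trec <- records[[ids[length(ids)]]]
  direct <- smith_waterman(qrec, trec, cfg$scheme)$alignment
  sel <- select_alignment(via$pairwise, direct)
  c(sel, list(merged = via$merged, via = via$pairwise, direct = direct))
}
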