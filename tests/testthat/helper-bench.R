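# Shared synthetic-benchmark builders used by module tests (at small sizes)
# and by the acceptance suite (at the sizes the criteria state).

# All sequences a family contributes, as a named record list (for alignment).
family_records <- function(fam) {
  stats::setNames(fam$chain, fam$ids)
}

# A multi-query detection benchmark: each query is the root of its own
# superfamily; the final database holds the family template plus two further
# relatives of it, among unrelated decoys; intermediate databases hold the
# chain intermediates plus decoys. Classification codes put each family in
# its own class-a superfamily and every decoy in its own class-x superfamily.
build_benchmark <- function(seed, n_queries = 20L, len = 120L,
                            n_decoys_final = 30L, n_decoys_int = 10L) {
  set.seed(seed)
  queries <- list(); q_sccs <- character()
  i1 <- list(); i2 <- list(); finals <- list(); f_sccs <- character()
  for (f in seq_len(n_queries)) {
    fam <- generate_family(seed * 1000L + f, len, 2L, 0.55, 0.02,
                           id_prefix = sprintf("f%02d", f))
    sf <- sprintf("a.%d.1", f)
    queries[[f]] <- fam$chain[[1L]]
    q_sccs[fam$ids[1L]] <- paste0(sf, ".1")
    i1[[length(i1) + 1L]] <- fam$chain[[2L]]
    i2[[length(i2) + 1L]] <- fam$chain[[3L]]
    finals[[length(finals) + 1L]] <- fam$chain[[4L]]
    f_sccs[fam$ids[4L]] <- paste0(sf, ".1")
    for (r in 1:2) {
      d <- derive_homolog(fam$chain[[4L]], 0.6, 0.02,
                          sprintf("%s_rel%d", fam$ids[4L], r))
      finals[[length(finals) + 1L]] <- d$record
      f_sccs[d$record$id] <- sprintf("%s.%d", sf, r + 1L)
    }
  }
  for (d in seq_len(n_decoys_final)) {
    rec <- seq_record(sprintf("dec_final_%02d", d), rand_prot(len))
    finals[[length(finals) + 1L]] <- rec
    f_sccs[rec$id] <- sprintf("x.%d.1.1", d)
  }
  for (d in seq_len(n_decoys_int)) {
    i1[[length(i1) + 1L]] <- seq_record(sprintf("dec_i1_%02d", d), rand_prot(len))
    i2[[length(i2) + 1L]] <- seq_record(sprintf("dec_i2_%02d", d), rand_prot(len))
  }
  list(queries = queries, query_sccs = q_sccs,
       db1 = seq_database(i1, "int1"), db2 = seq_database(i2, "int2"),
       final = seq_database(finals, "final", classification = f_sccs))
}

# Search function (query -> ranked subject ids) for a k-layer ISS over a
# benchmark, with modest per-layer hit caps to keep the path set small.
bench_search_fun <- function(bench, k, caps = 8L) {
  cfg <- iss_config(k, max_hits_per_layer = c(rep(caps, k), 100L))
  idbs <- list(bench$db1, bench$db2)[seq_len(k)]
  function(q) {
    vapply(rank_hits(iss_search(q, idbs, bench$final, cfg)),
           function(rh) rh$subject_id, "")
  }
}

# One sub-region-narrowing scenario: a two-superfamily world whose only
# intermediate is a multi-domain decoy gluing family A's intermediate to
# family B's intermediate. Returns the count of final hits outside A's
# superfamily for sub-region vs whole-sequence re-querying.
narrowing_false_positives <- function(seed, len = 120L) {
  famA <- generate_family(seed, len, 1L, 0.55, 0.02, id_prefix = "A")
  famB <- generate_family(seed + 500000L, len, 1L, 0.55, 0.02, id_prefix = "B")
  decoy <- make_multidomain_decoy(famA, seed = seed,
                                  unrelated_seq = famB$chain[[2L]]$residues,
                                  id = "decoyAB")
  idb <- seq_database(list(decoy), "intermediates")
  finals <- list(famA$chain[[3L]], famB$chain[[3L]])
  f_sccs <- c("a.1.1.1", "b.1.1.1")
  set.seed(seed)
  for (r in 1:2) {
    d <- derive_homolog(famB$chain[[3L]], 0.6, 0.02, sprintf("B_rel%d", r))
    finals[[length(finals) + 1L]] <- d$record
    f_sccs <- c(f_sccs, sprintf("b.1.1.%d", r + 1L))
  }
  names(f_sccs) <- vapply(finals, function(r) r$id, "")
  fdb <- seq_database(finals, "final", classification = f_sccs)
  # The final cutoff must be a *significant* threshold: at the permissive
  # default (10) both routes additionally retrieve the same noise-level hits
  # and the narrowing shows up only in path scores, not in set membership.
  count_false <- function(use_sub) {
    cfg <- iss_config(1L, evalue_cutoffs = c(1e-3, 1e-3),
                      use_subregions = use_sub)
    ranked <- rank_hits(iss_search(famA$chain[[1L]], list(idb), fdb, cfg))
    ids <- vapply(ranked, function(rh) rh$subject_id, "")
    sum(!vapply(f_sccs[ids], function(s) superfamily_label("a.1.1.1", s), TRUE))
  }
  c(subregion = count_false(TRUE), whole = count_false(FALSE))
}
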