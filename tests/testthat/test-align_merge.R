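test_that("compose_maps follows the definition and the identity law", {
  m1 <- residue_map("a", "b", c(0, 1, 4), c(2, 3, 5))
  m2 <- residue_map("b", "c", c(2, 5), c(0, 1))
  m <- compose_maps(m1, m2)
  expect_equal(m$i, c(0L, 4L))
  expect_equal(m$j, c(0L, 1L))
  expect_equal(m$source_id, "a")
  expect_equal(m$target_id, "c")

  idm <- issalign:::identity_map("b", "b", m1$j)
  expect_equal(map_pairs_key(compose_maps(m1, idm)), map_pairs_key(m1))

  expect_error(compose_maps(m1, residue_map("z", "c", 0, 0)), "composition")
})

test_that("composition matches the brute-force oracle and is associative", {
  set.seed(55)
  for (k in 1:120) {
    a <- rand_map("a", "b", sample(0:15, 1) + 1)
    b <- rand_map("b", "c", sample(0:15, 1) + 1)
    c3 <- rand_map("c", "d", sample(0:15, 1) + 1)
    ab <- compose_maps(a, b)
    expect_equal(map_pairs_key(ab), map_pairs_key(compose_oracle(a, b)))
    expect_true(all(diff(ab$i) > 0) && all(diff(ab$j) > 0) || map_size(ab) <= 1)
    lhs <- compose_maps(compose_maps(a, b), c3)
    rhs <- compose_maps(a, compose_maps(b, c3))
    expect_equal(map_pairs_key(lhs), map_pairs_key(rhs))
  }
})

test_that("an identity chain yields the full identity alignment", {
  s <- rand_prot(60)
  recs <- list(Q = seq_record("Q", s), I = seq_record("I", s),
               T = seq_record("T", s))
  h1 <- search_hit("Q", "I", region("Q", 0, 60), region("I", 0, 60), 1e-30, layer = 0)
  h2 <- search_hit("I", "T", region("I", 0, 60), region("T", 0, 60), 1e-30, layer = 1)
  res <- chain_to_alignment(search_path(list(h1, h2)), recs, iss_config(1))
  expect_equal(res$pairwise$a_row, s)
  expect_equal(res$pairwise$b_row, s)
  expect_equal(aligned_region_length(res$pairwise), 60L)
  expect_equal(res$merged$rows, rep(s, 3))
})

test_that("an exact-copy intermediate projects the direct alignment through", {
  set.seed(56)
  fam <- generate_family(56, 120, 0, 0.5, 0.02)
  q <- fam$chain[[1]]; t <- fam$chain[[2]]
  i <- seq_record("Icopy", q$residues)  # intermediate = copy of the query
  recs <- stats::setNames(list(q, i, t), c(q$id, "Icopy", t$id))
  cfg <- iss_config(1)
  h1 <- search_hit(q$id, "Icopy", region(q$id, 0, q$length),
                   region("Icopy", 0, i$length), 1e-40, layer = 0)
  sw <- smith_waterman(i, t, cfg$scheme)
  h2 <- search_hit("Icopy", t$id, sw$query_region, sw$subject_region,
                   1e-10, layer = 1)
  res <- chain_to_alignment(search_path(list(h1, h2)), recs, cfg)
  # matched pairs must equal those of the direct SW on the (extended) regions
  breg <- extend_region(sw$subject_region, 20, t$length)
  direct <- smith_waterman(q, issalign:::sub_record(t, breg$start, breg$end),
                           cfg$scheme)
  dm <- residue_map_from_alignment(direct$alignment, 0, breg$start)
  cm <- residue_map_from_alignment(res$pairwise)
  expect_equal(map_pairs_key(cm), map_pairs_key(dm))
})

test_that("merged alignment preserves every edge's pairwise alignment", {
  for (seed in c(57, 58, 59)) {
    fam <- generate_family(seed, 130, 2, 0.55, 0.02)
    recs <- family_records(fam)
    paths <- iss_search(fam$chain[[1]],
                        list(seq_database(list(fam$chain[[2]])),
                             seq_database(list(fam$chain[[3]]))),
                        seq_database(list(fam$chain[[4]])), iss_config(2))
    full <- Filter(function(p) length(p$hits) == 3L, paths)
    if (!length(full)) next
    res <- chain_to_alignment(full[[1]], recs, iss_config(2))
    expect_false(is.null(res$merged))
    rows <- res$merged$rows
    expect_length(unique(nchar(rows)), 1L)
    # ungapped rows are contiguous sub-sequences
    for (r in seq_along(rows)) {
      ung <- gsub("-", "", rows[r])
      expect_true(grepl(ung, recs[[res$merged$ids[r]]]$residues, fixed = TRUE))
    }
    # adjacent-row matched pairs reproduce each edge map exactly
    row_start <- function(row, rec)
      as.integer(regexpr(gsub("-", "", row), rec$residues, fixed = TRUE)) - 1L
    for (e in seq_along(res$edge_alignments)) {
      edge <- res$edge_alignments[[e]]
      ra <- strsplit(rows[e], "")[[1]]
      rb <- strsplit(rows[e + 1], "")[[1]]
      keep <- !(ra == "-" & rb == "-")
      restr <- pairwise_alignment(edge$a_id, edge$b_id,
                                  row_start(rows[e], recs[[res$merged$ids[e]]]),
                                  row_start(rows[e + 1], recs[[res$merged$ids[e + 1]]]),
                                  paste(ra[keep], collapse = ""),
                                  paste(rb[keep], collapse = ""))
      got <- residue_map_from_alignment(restr)
      want <- residue_map_from_alignment(edge)
      expect_equal(map_pairs_key(got), map_pairs_key(want))
    }
  }
})

test_that("selection always keeps the longer aligned region, ties to intermediates", {
  a50 <- alignment_from_map(residue_map("q", "t", 0:49, 0:49),
                            seq_record("q", rand_prot(60)),
                            seq_record("t", rand_prot(60)))
  a30 <- alignment_from_map(residue_map("q", "t", 0:29, 0:29),
                            seq_record("q", rand_prot(60)),
                            seq_record("t", rand_prot(60)))
  expect_equal(select_alignment(a50, a30)$provenance, "intermediate")
  expect_equal(select_alignment(a30, a50)$provenance, "direct")
  expect_equal(select_alignment(a30, a50)$alignment$a_row, a50$a_row)
  expect_equal(select_alignment(a30, a30)$provenance, "intermediate")
})

test_that("aligned_region_length counts matched columns only", {
  expect_equal(aligned_region_length(issalign:::empty_alignment("a", "b")), 0L)
  full <- pairwise_alignment("a", "b", 0, 0, strrep("A", 40), strrep("A", 40))
  expect_equal(aligned_region_length(full), 40L)
  gapped <- pairwise_alignment("a", "b", 0, 0,
                               paste0(strrep("A", 30), strrep("-", 10)),
                               paste0(strrep("A", 30), strrep("C", 10)))
  expect_equal(aligned_region_length(gapped), 30L)
})

test_that("unresolvable ids and empty compositions are handled", {
  h <- search_hit("q", "t", region("q", 0, 5), region("t", 0, 5), 1, layer = 0)
  expect_error(chain_to_alignment(search_path(list(h)), list(), iss_config(0)),
               "unresolvable")
})
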