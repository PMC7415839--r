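test_that("extend_region widens and clamps", {
  expect_equal(unlist(extend_region(region("s", 10, 20), 5, 100)[c("start", "end")]),
               c(start = 5L, end = 25L))
  expect_equal(unlist(extend_region(region("s", 2, 8), 5, 50)[c("start", "end")]),
               c(start = 0L, end = 13L))
  expect_equal(unlist(extend_region(region("s", 90, 98), 20, 100)[c("start", "end")]),
               c(start = 70L, end = 100L))
})

test_that("iss_config validates arity and defaults per layer", {
  cfg <- iss_config(2)
  expect_equal(cfg$extension_lengths, c(5L, 5L, 20L))
  expect_equal(cfg$evalue_cutoffs, c(1e-3, 1e-3, 10))
  expect_error(iss_config(2, extension_lengths = c(5, 20)), "extension_lengths")
  expect_error(iss_config(1, evalue_cutoffs = c(0, 10)), "evalue_cutoffs")
})

test_that("0 intermediate layers reduces to a wrapped direct search", {
  set.seed(21)
  q <- seq_record("q", rand_prot(60))
  fdb <- seq_database(c(list(seq_record("near", q$residues)),
                        lapply(1:4, function(k)
                          seq_record(paste0("r", k), rand_prot(60)))))
  cfg <- iss_config(0)
  paths <- iss_search(q, list(), fdb, cfg)
  direct <- scan_search(q, fdb, cfg$scheme, cfg$evalue_cutoffs[1],
                        cfg$max_hits_per_layer[1])
  expect_equal(length(paths), length(direct))
  expect_true(all(vapply(paths, function(p) length(p$hits), 0L) == 1L))
  expect_equal(sort(vapply(paths, function(p) p$hits[[1]]$subject_id, "")),
               sort(vapply(direct, function(h) h$subject_id, "")))
})

test_that("a remote template unreachable directly is reached through an intermediate", {
  fam <- generate_family(34, 140, 1, 0.40, 0.02)
  q <- fam$chain[[1]]; i1 <- fam$chain[[2]]; t <- fam$chain[[3]]
  idb <- seq_database(list(i1)); fdb <- seq_database(list(t))
  cfg <- iss_config(1, evalue_cutoffs = c(1e-10, 1e-4))
  direct <- scan_search(q, fdb, cfg$scheme, 1e-4, 100)
  expect_length(direct, 0)  # the direct route genuinely misses the template
  paths <- iss_search(q, list(idb), fdb, cfg)
  expect_true(any(vapply(paths, function(p) length(p$hits) == 2L, TRUE)))
  ids <- issalign:::path_ids(paths[[1]])
  expect_equal(ids[1], q$id)
  expect_equal(ids[length(ids)], t$id)
})

test_that("paths never revisit the query id even if it sits in a database", {
  fam <- generate_family(32, 120, 1, 0.6, 0.01)
  q <- fam$chain[[1]]
  idb <- seq_database(list(fam$chain[[2]], q))   # query planted as db record
  fdb <- seq_database(list(fam$chain[[3]], q))
  paths <- iss_search(q, list(idb), fdb, iss_config(1))
  for (p in paths) expect_equal(sum(issalign:::path_ids(p) == q$id), 1L)
})

test_that("rank_hits keeps the best path per subject and sorts ascending", {
  mk <- function(ids, evs) {
    hits <- lapply(seq_along(evs), function(k)
      search_hit(ids[k], ids[k + 1],
                 region(ids[k], 0, 10), region(ids[k + 1], 0, 10),
                 evs[k], layer = k - 1))
    search_path(hits)
  }
  p1 <- mk(c("q", "i1", "X"), c(0.4, 0.1))    # sum 0.5
  p2 <- mk(c("q", "i2", "X"), c(0.005, 0.005))  # sum 0.01 (best for X)
  p3 <- mk(c("q", "Y"), 0.5)
  rk <- rank_hits(list(p1, p2, p3))
  expect_equal(vapply(rk, function(r) r$subject_id, ""), c("X", "Y"))
  expect_equal(rk[[1]]$score, 0.01)
  expect_equal(issalign:::path_ids(rk[[1]]$best_path), c("q", "i2", "X"))
  expect_equal(vapply(rk, function(r) r$rank, 0L), 1:2)
  expect_length(rank_hits(list()), 0)
})

test_that("reachability is monotone in depth when cutoffs and caps bind nothing", {
  set.seed(33)
  fam <- generate_family(33, 100, 2, 0.6, 0.01)
  idb1 <- seq_database(list(fam$chain[[2]]))
  idb2 <- seq_database(list(fam$chain[[3]]))
  fdb <- seq_database(c(list(fam$chain[[4]]),
                        lapply(1:3, function(k)
                          seq_record(paste0("r", k), rand_prot(100)))))
  loose <- function(k) iss_config(k, evalue_cutoffs = rep(1e6, k + 1),
                                  max_hits_per_layer = rep(1000L, k + 1))
  reach <- function(k, idbs) {
    unique(vapply(rank_hits(iss_search(fam$chain[[1]], idbs, fdb, loose(k))),
                  function(r) r$subject_id, ""))
  }
  r0 <- reach(0, list())
  r1 <- reach(1, list(idb1))
  r2 <- reach(2, list(idb1, idb2))
  expect_true(all(r0 %in% r1))
  expect_true(all(r1 %in% r2))
})

test_that("identical inputs give identical ranked output", {
  fam <- generate_family(34, 110, 1, 0.55, 0.02)
  idb <- seq_database(list(fam$chain[[2]]))
  fdb <- seq_database(list(fam$chain[[3]]))
  run <- function() ranked_hits_table(rank_hits(
    iss_search(fam$chain[[1]], list(idb), fdb, iss_config(1))))
  expect_identical(run(), run())
})

test_that("engine failures carry layer context", {
  bad_engine <- function(...) stop("backend exploded")
  fam <- generate_family(35, 100, 0, 0.6, 0.01)
  fdb <- seq_database(list(fam$chain[[2]]))
  expect_error(iss_search(fam$chain[[1]], list(), fdb, iss_config(0),
                          engine = bad_engine), "layer 0")
})
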