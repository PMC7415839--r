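test_that("scan_search ranks an identical record first with maximal bitscore", {
  set.seed(11)
  q <- seq_record("q", rand_prot(50))
  db <- seq_database(c(list(seq_record("twin", q$residues)),
                       lapply(1:5, function(k)
                         seq_record(paste0("r", k), rand_prot(50)))))
  hits <- scan_search(q, db, evalue_cutoff = 10)
  expect_equal(hits[[1]]$subject_id, "twin")
  expect_true(all(vapply(hits[-1], function(h) h$evalue, 0) >= hits[[1]]$evalue))
})

test_that("unrelated random sequences do not survive a stringent cutoff", {
  set.seed(12)
  q <- seq_record("q", rand_prot(60))
  db <- seq_database(lapply(1:10, function(k)
    seq_record(paste0("r", k), rand_prot(60))))
  # verify directly that no raw score reaches the E <= 1e-6 threshold
  for (rec in db$records) {
    s <- smith_waterman(q, rec)$score
    expect_gt(evalue_from_score(s, 60, 60), 1e-6)
  }
  expect_length(scan_search(q, db, evalue_cutoff = 1e-6), 0)
})

test_that("max_hits truncates to the smallest E-values", {
  set.seed(13)
  base <- rand_prot(80)
  db <- seq_database(lapply(1:10, function(k) {
    ch <- strsplit(base, "")[[1]]
    ch[sample(80, 5 * k)] <- sample(.AA20, 5 * k, replace = TRUE)
    seq_record(paste0("m", k), paste(ch, collapse = ""))
  }))
  q <- seq_record("q", base)
  all10 <- scan_search(q, db, evalue_cutoff = 10, max_hits = 100)
  expect_length(all10, 10)
  top3 <- scan_search(q, db, evalue_cutoff = 10, max_hits = 3)
  expect_length(top3, 3)
  expect_equal(vapply(top3, function(h) h$evalue, 0),
               vapply(all10[1:3], function(h) h$evalue, 0))
})

test_that("self-hits are excluded and sub-region coordinates are lifted", {
  set.seed(14)
  q <- seq_record("q", rand_prot(80))
  db <- seq_database(list(q, seq_record("copy", q$residues)))
  hits <- scan_search(q, db, evalue_cutoff = 10)
  expect_equal(vapply(hits, function(h) h$subject_id, ""), "copy")
  sub <- scan_search(q, db, evalue_cutoff = 10,
                     query_region = region("q", 20, 60))
  expect_equal(sub[[1]]$query_region$start, 20L)
  expect_equal(sub[[1]]$query_region$end, 60L)
  expect_equal(sub[[1]]$subject_region$start, 20L)
})

test_that("E-values decrease strictly with score at fixed lengths", {
  e <- evalue_from_score(10:60, 100, 100)
  expect_true(all(diff(e) < 0))
  expect_error(scan_search(seq_record("q", "ACDE"),
                           seq_database(list(seq_record("s", "ACDE"))),
                           evalue_cutoff = 0), "positive")
})

test_that("parse_tabular_hits converts coordinates and collapses HSPs", {
  h <- parse_tabular_hits("q1 s1 1e-5 50.1 1 10 5 14")
  expect_length(h, 1)
  expect_equal(c(h[[1]]$query_region$start, h[[1]]$query_region$end), c(0L, 10L))
  expect_equal(c(h[[1]]$subject_region$start, h[[1]]$subject_region$end), c(4L, 14L))
  expect_equal(h[[1]]$evalue, 1e-5)

  two <- parse_tabular_hits(c("q1 s1 1e-3 20 1 10 1 10",
                              "q1 s1 1e-8 60 2 12 3 13"))
  expect_length(two, 1)
  expect_equal(two[[1]]$evalue, 1e-8)

  expect_length(parse_tabular_hits(character()), 0)
  expect_error(parse_tabular_hits("q1 s1 1e-5 50.1 1 10 5"), "line 1")
  expect_error(parse_tabular_hits(c("q1 s1 1e-5 50.1 1 10 5 14",
                                    "q1 s2 bad 50.1 1 10 5 14")), "line 2")
  expect_error(parse_tabular_hits("q1 s1 1e-5 50.1 0 10 5 14"), "line 1")
})

test_that("both engines satisfy the search-engine contract", {
  set.seed(15)
  base <- rand_prot(70)
  recs <- lapply(1:8, function(k) {
    ch <- strsplit(base, "")[[1]]
    ch[sample(70, 6 * k)] <- sample(.AA20, 6 * k, replace = TRUE)
    seq_record(paste0("s", k), paste(ch, collapse = ""))
  })
  db <- seq_database(recs)
  q <- seq_record("q", base)
  tab_lines <- vapply(seq_along(recs), function(k)
    sprintf("q s%d %g %g 1 70 1 70", k, 10^(-k), 30 + k), "")
  engines <- list(scan = scan_engine(),
                  tabular = tabular_engine(parse_tabular_hits(tab_lines)))
  for (nm in names(engines)) {
    for (cutoff in c(1e-4, 1)) {
      hits <- engines[[nm]](q, NULL, db, cutoff, 5L, 0L)
      ev <- vapply(hits, function(h) h$evalue, 0)
      expect_true(all(diff(ev) >= 0), info = nm)        # ascending E-values
      expect_true(all(ev <= cutoff), info = nm)         # cutoff respected
      expect_lte(length(hits), 5L)                      # cap respected
      expect_false(any(vapply(hits, function(h) h$subject_id, "") == "q"),
                   info = nm)
    }
  }
})
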