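# Homology-detection evaluation: SCOP-style superfamily truth labels and the
# truncated-ROC metric AUC_n, which only considers results up to the n-th
# false positive and normalizes to [0, 1].

#' Same-superfamily test for sccs codes
#'
#' A detection counts as a true positive when query and subject belong to the
#' same SCOP superfamily, i.e. when the first three dot-separated fields of
#' their sccs codes (class.fold.superfamily) are equal.
#'
#' @param query_sccs,subject_sccs Dot-separated sccs codes with at least
#'   three fields (e.g. `"a.1.1.1"`).
#' @return Logical flag.
#' @export
superfamily_label <- function(query_sccs, subject_sccs) {
  split3 <- function(x) {
    f <- strsplit(x, ".", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("classification parse error: '", x, "' has fewer than 3 fields")
    f[1:3]
  }
  identical(split3(query_sccs), split3(subject_sccs))
}

#' Truncated ROC area AUC_n
#'
#' `AUC_n = sum_{i=1..n} t_i / (n * T)` where `t_i` is the number of true
#' positives ranked above the i-th false positive and `T` is the total number
#' of homologs of the query in the searched database (retrieved or not). If
#' the ranking contains fewer than `n` false positives, the missing `t_i`
#' equal the total number of true positives retrieved (unretrieved entries
#' are treated as ranked after everything).
#'
#' @param is_tp Logical vector: the ranking's entries, in descending
#'   confidence order, flagged as true positives.
#' @param n_true_total `T`, the number of true homologs in the database
#'   (>= 1; `T = 0` makes the metric undefined and is an error).
#' @param n The false-positive cutoff (>= 1).
#' @return AUC_n in [0, 1].
#' @examples
#' auc_n(c(TRUE, FALSE, TRUE, FALSE), n_true_total = 2, n = 2)  # 0.75
#' @export
auc_n <- function(is_tp, n_true_total, n) {
  if (n_true_total < 1) stop("undefined metric: no true homologs in database")
  if (n < 1) stop("n must be >= 1")
  is_tp <- as.logical(is_tp)
  cum_tp <- cumsum(is_tp)
  fp_at <- which(!is_tp)
  t_i <- if (length(fp_at)) cum_tp[fp_at] else numeric()
  if (length(t_i) >= n) {
    t_i <- t_i[seq_len(n)]
  } else {
    t_i <- c(t_i, rep(sum(is_tp), n - length(t_i)))
  }
  sum(t_i) / (n * n_true_total)
}

#' Evaluate ranked retrieval over a query set
#'
#' Runs a search function for each query, labels the ranked subjects by
#' same-superfamily truth against the database classification, and computes
#' AUC_n for each cutoff. Self-hits are removed before labeling. `T` counts
#' all same-superfamily database entries (other than the query itself),
#' whether retrieved or not; a query with no homolog in the database is
#' skipped with a warning.
#'
#' @param queries List of [seq_record()] objects.
#' @param db A [seq_database()] with classification for all entries.
#' @param search_fun Function `seq_record -> character vector` of subject ids
#'   in descending confidence order.
#' @param n_values Integer vector of AUC cutoffs (default
#'   `c(10, 50, 100, 250, 500)`).
#' @param query_sccs Optional named character vector giving sccs codes for
#'   queries not present in `db`.
#' @return A data.frame with columns `query_id`, `n`, `auc`, one row per
#'   (query, cutoff).
#' @export
evaluate_queries <- function(queries, db, search_fun,
                             n_values = c(10L, 50L, 100L, 250L, 500L),
                             query_sccs = NULL) {
  stopifnot(inherits(db, "seq_database"))
  cls <- db$classification
  if (is.null(cls)) stop("database has no classification")
  if (length(setdiff(names(db$records), names(cls))))
    stop("classification must cover all database entries")
  out <- list()
  for (q in queries) {
    qc <- if (q$id %in% names(cls)) cls[[q$id]]
          else if (!is.null(query_sccs) && q$id %in% names(query_sccs))
            query_sccs[[q$id]]
          else stop("no classification for query '", q$id, "'")
    others <- setdiff(names(db$records), q$id)
    truth <- vapply(others, function(s) superfamily_label(qc, cls[[s]]), TRUE)
    T_total <- sum(truth)
    if (T_total == 0L) {
      warning("query '", q$id, "' has no same-superfamily entry; skipped")
      next
    }
    ranked <- search_fun(q)
    ranked <- ranked[ranked != q$id]
    is_tp <- unname(truth[match(ranked, others)])
    for (n in n_values) {
      out[[length(out) + 1L]] <- data.frame(
        query_id = q$id, n = as.integer(n),
        auc = auc_n(is_tp, T_total, n), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(), n = integer(), auc = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
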