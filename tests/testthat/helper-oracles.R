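# Independent oracles and small random-input generators. These deliberately
# re-derive expected values by the most transparent route available (plain-R
# DP, brute-force double loops) and never call the code paths they check.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

rand_prot <- function(len) paste(sample(.AA20, len, replace = TRUE), collapse = "")

# Reference affine-gap local-alignment score: plain-R Gotoh DP, score only.
sw_oracle_score <- function(a, b, scheme = scoring_scheme()) {
  mat <- scheme$matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)
  FF <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i - 1L, j] - open, E[i - 1L, j] - ext)
      FF[i, j] <- max(H[i, j - 1L] - open, FF[i, j - 1L] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[A[i - 1L], B[j - 1L]],
                     E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Brute-force map composition: all pair combinations, double loop.
compose_oracle <- function(m1, m2) {
  ii <- integer(); jj <- integer()
  for (x in seq_along(m1$i)) {
    for (y in seq_along(m2$i)) {
      if (m1$j[x] == m2$i[y]) {
        ii <- c(ii, m1$i[x]); jj <- c(jj, m2$j[y])
      }
    }
  }
  residue_map(m1$source_id, m2$target_id, ii, jj)
}

# Random strictly monotone partial map with n_pairs pairs drawn on [0, range).
rand_map <- function(src, tgt, n_pairs, range = 40L) {
  residue_map(src, tgt,
              sort(sample(0:(range - 1L), n_pairs)),
              sort(sample(0:(range - 1L), n_pairs)))
}

map_pairs_key <- function(m) paste(m$i, m$j, sep = ",")
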