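# Synthetic remote-homolog families with exact ground-truth residue
# correspondences: the desk-scale stand-in for UniRef/SCOP-style material.
# A family is a chain Q -> I1 -> ... -> Ik -> T in which each sequence
# derives from the previous by substitutions (sampled with BLOSUM62-biased
# probabilities, so synthetic homology stays detectable by score-based
# search) and geometric-length indels; every edit is tracked, so the true
# residue map of every sequence pair is known exactly.

# Robinson-Robinson amino-acid background frequencies.
.AA_BG <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
            Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
            L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
            S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)

random_protein <- function(length) {
  paste(sample(names(.AA_BG), length, replace = TRUE, prob = .AA_BG),
        collapse = "")
}

#' Derive a homologous sequence
#'
#' Produces a descendant of `record` at approximately the target fractional
#' identity: `round((1 - identity) * L)` positions are substituted (the
#' replacement residue drawn with probability proportional to
#' `background * exp(s/2)` for BLOSUM62 score `s`, never the original
#' residue), then `Poisson(indel_rate * L)` indels of geometric length
#' (mean 2) are applied, kept at least 3 residues from the sequence ends.
#' The exact parent-to-child residue correspondence is returned alongside.
#'
#' @param record Parent [seq_record()].
#' @param identity Target fractional identity in (0, 1).
#' @param indel_rate Expected indels per site.
#' @param new_id Identifier for the derived record.
#' @param scheme [scoring_scheme()] providing the substitution bias.
#' @return A list with `record` (the child [seq_record()]) and `map` (the
#'   parent-to-child [residue_map()]).
#' @export
derive_homolog <- function(record, identity, indel_rate, new_id,
                           scheme = scoring_scheme()) {
  if (identity <= 0 || identity >= 1)
    stop("identity must be in (0, 1)")
  if (indel_rate < 0) stop("indel_rate must be nonnegative")
  aa <- names(.AA_BG)
  mat <- scheme$matrix[aa, aa]
  ch <- strsplit(record$residues, "")[[1L]]
  L <- length(ch)
  n_sub <- round((1 - identity) * L)
  if (n_sub >= L) stop("identity target unreachable for length ", L)
  if (n_sub > 0L) {
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      a <- ch[p]
      if (!(a %in% aa)) a <- sample(aa, 1L)
      w <- .AA_BG * exp(mat[a, ] / 2)
      w[a] <- 0
      ch[p] <- sample(aa, 1L, prob = w)
    }
  }
  # childpos[i] = current 0-based child index of parent residue i, or NA
  childpos <- seq_along(ch) - 1L
  child <- ch
  n_ind <- stats::rpois(1L, indel_rate * L)
  for (k in seq_len(n_ind)) {
    Lc <- length(child)
    len <- 1L + stats::rgeom(1L, 0.5)
    if (stats::runif(1L) < 0.5) {
      # insertion after 0-based position p, with p in [3, Lc - 3]
      if (Lc < 7L) next
      p <- sample(3:(Lc - 3L), 1L)
      ins <- sample(aa, len, replace = TRUE, prob = .AA_BG)
      child <- append(child, ins, after = p)
      childpos <- ifelse(!is.na(childpos) & childpos >= p, childpos + len,
                         childpos)
    } else {
      # deletion of [s, s + len) staying 3 residues from both ends
      if (Lc - len < 7L) next
      lo <- 3L; hi <- Lc - 3L - len
      if (hi < lo) next
      s <- sample(lo:hi, 1L)
      child <- child[-((s + 1L):(s + len))]
      childpos <- ifelse(!is.na(childpos) & childpos >= s & childpos < s + len,
                         NA_integer_, childpos)
      childpos <- ifelse(!is.na(childpos) & childpos >= s + len,
                         childpos - len, childpos)
    }
  }
  keep <- !is.na(childpos)
  list(record = seq_record(new_id, paste(child, collapse = "")),
       map = residue_map(record$id, new_id,
                         (seq_along(ch) - 1L)[keep], childpos[keep]))
}

# Fractional identity of a mapped pair of sequences, measured over the map.
map_identity <- function(map, rec_a, rec_b) {
  if (map_size(map) == 0L) return(0)
  ca <- strsplit(rec_a$residues, "")[[1L]]
  cb <- strsplit(rec_b$residues, "")[[1L]]
  mean(ca[map$i + 1L] == cb[map$j + 1L])
}

#' Generate a synthetic remote-homolog family
#'
#' Builds the chain Q, I1, ..., Ik, T by successive [derive_homolog()] steps
#' from a random ancestor. True residue maps for every ordered pair in the
#' chain are stored (forward maps composed step-wise; reverse maps are the
#' inverses). Identical seeds give byte-identical families.
#'
#' @param seed Integer seed controlling all randomness.
#' @param ancestor_length Length of the ancestor/query (>= 30; default 150).
#' @param n_intermediates Number of intermediate sequences k (default 2).
#' @param branch_identity Target per-step fractional identity (default 0.55).
#' @param indel_rate Expected indels per site per step (default 0.02).
#' @param id_prefix Prefix for the generated sequence ids.
#' @param scheme [scoring_scheme()] for the substitution bias.
#' @return An object of class `synthetic_family`: `chain` (list of
#'   [seq_record()]), `true_maps` (named list, keys `"<from>|<to>"`),
#'   `step_identities` (measured per-step identities), plus the generator
#'   parameters. Access maps with [true_map()].
#' @export
generate_family <- function(seed, ancestor_length = 150L, n_intermediates = 2L,
                            branch_identity = 0.55, indel_rate = 0.02,
                            id_prefix = "fam", scheme = scoring_scheme()) {
  if (ancestor_length < 30L) stop("ancestor_length must be >= 30")
  if (branch_identity <= 0 || branch_identity >= 1)
    stop("branch_identity must be in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  labels <- c("Q", if (n_intermediates > 0) paste0("I", seq_len(n_intermediates)), "T")
  ids <- paste0(id_prefix, "_", labels)
  chain <- list(seq_record(ids[1L], random_protein(ancestor_length)))
  step_maps <- list()
  for (s in seq_len(n_intermediates + 1L)) {
    d <- derive_homolog(chain[[s]], branch_identity, indel_rate, ids[s + 1L],
                        scheme)
    chain[[s + 1L]] <- d$record
    step_maps[[s]] <- d$map
  }

  nseq <- length(chain)
  true_maps <- list()
  for (a in seq_len(nseq - 1L)) {
    m <- NULL
    for (b in (a + 1L):nseq) {
      m <- if (is.null(m)) step_maps[[a]] else compose_maps(m, step_maps[[b - 1L]])
      true_maps[[paste0(ids[a], "|", ids[b])]] <- m
      true_maps[[paste0(ids[b], "|", ids[a])]] <-
        residue_map(ids[b], ids[a], m$j, m$i)
    }
  }

  step_id <- vapply(seq_len(nseq - 1L), function(s)
    map_identity(step_maps[[s]], chain[[s]], chain[[s + 1L]]), 0)
  if (any(abs(step_id - branch_identity) > 0.10))
    stop("generation error: measured step identity strayed from target")

  structure(list(chain = chain, ids = ids, true_maps = true_maps,
                 step_identities = step_id,
                 branch_identity = branch_identity, indel_rate = indel_rate,
                 seed = seed, decoys = list()),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("<synthetic_family %s: branch identity %.2f, Q-T identity %.2f>\n",
              paste(x$ids, collapse = " -> "), x$branch_identity,
              family_qt_identity(x)))
  invisible(x)
}

#' Ground-truth residue map between two family members
#'
#' @param family A `synthetic_family`.
#' @param from_id,to_id Member ids.
#' @return The true [residue_map()].
#' @export
true_map <- function(family, from_id, to_id) {
  key <- paste0(from_id, "|", to_id)
  m <- family$true_maps[[key]]
  if (is.null(m)) stop("no true map for ", from_id, " -> ", to_id)
  m
}

#' Measured query-template identity of a family
#'
#' Fractional identity of the first and last chain members over their true
#' residue map.
#'
#' @param family A `synthetic_family`.
#' @return Fraction in [0, 1].
#' @export
family_qt_identity <- function(family) {
  n <- length(family$chain)
  map_identity(true_map(family, family$ids[1L], family$ids[n]),
               family$chain[[1L]], family$chain[[n]])
}

#' Multi-domain decoy sequence
#'
#' Concatenates a family-derived homologous domain (the first intermediate,
#' or the template for an intermediate-free family) with an unrelated domain,
#' emulating the multi-domain database entries that cause ISS false
#' positives. The domain boundary, the source id and the identity map of the
#' homologous half are attached as attributes (`boundary`,
#' `homolog_source`, `homolog_map`).
#'
#' @param family A `synthetic_family`.
#' @param unrelated_length Length of the unrelated domain (ignored when
#'   `unrelated_seq` is given).
#' @param seed Integer seed.
#' @param unrelated_seq Optional explicit residue string for the unrelated
#'   domain (e.g. a member of a different family, so the decoy links two real
#'   superfamilies).
#' @param id Identifier for the decoy record.
#' @return A [seq_record()] with the attributes described above.
#' @export
make_multidomain_decoy <- function(family, unrelated_length = 100L, seed = 1L,
                                   unrelated_seq = NULL, id = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  src <- family$chain[[2L]]
  if (is.null(unrelated_seq)) unrelated_seq <- random_protein(unrelated_length)
  if (is.null(id)) id <- paste0(src$id, "_decoy", seed)
  rec <- seq_record(id, paste0(src$residues, unrelated_seq))
  attr(rec, "boundary") <- src$length
  attr(rec, "homolog_source") <- src$id
  attr(rec, "homolog_map") <- identity_map(id, src$id, seq_len(src$length) - 1L)
  rec
}

#' Precision and recall of a predicted residue map
#'
#' Compares a predicted residue correspondence against the ground truth:
#' precision is the fraction of predicted pairs that are true (0 for an
#' empty prediction), recall the fraction of true pairs predicted. An empty
#' truth map leaves recall undefined and is an error.
#'
#' @param predicted,truth [residue_map()] objects over the same sequence
#'   pair.
#' @return Named numeric vector `c(precision =, recall =)`.
#' @export
true_pair_accuracy <- function(predicted, truth) {
  if (map_size(truth) == 0L) stop("undefined recall: empty truth map")
  if (map_size(predicted) == 0L)
    return(c(precision = 0, recall = 0))
  pk <- paste(predicted$i, predicted$j)
  tk <- paste(truth$i, truth$j)
  inter <- sum(pk %in% tk)
  c(precision = inter / length(pk), recall = inter / length(tk))
}
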