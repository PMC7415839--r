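#' @useDynLib issalign, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# Coordinate convention, package-wide: 0-based, half-open [start, end).
# External 1-based inclusive dialects (BLAST tabular) are converted at the
# I/O boundary only. The gap symbol in emitted alignments is "-".

.AA_STANDARD <- "ACDEFGHIKLMNPQRSTVWY"

#' Amino-acid sequence record
#'
#' A named protein sequence. Residues are uppercased on construction and any
#' alphabetic character outside the 20-letter amino-acid alphabet is mapped to
#' `X`; non-alphabetic characters (including gap symbols) are an error.
#'
#' @param id Non-empty unique identifier.
#' @param residues Amino-acid string, length >= 1.
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `residues` and `length`.
#' @examples
#' seq_record("q1", "acdefu")$residues  # "ACDEFX"
#' @export
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L)
    stop("residues must be a single string")
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues))
    stop("sequence '", id, "' is empty")
  if (grepl("[^A-Z]", residues))
    stop("sequence '", id, "' contains non-sequence characters")
  std <- strsplit(.AA_STANDARD, "")[[1]]
  ch <- strsplit(residues, "")[[1]]
  ch[!(ch %in% c(std, "X"))] <- "X"
  residues <- paste(ch, collapse = "")
  structure(list(id = id, description = description, residues = residues,
                 length = nchar(residues)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s: %d aa>\n", x$id, x$length))
  invisible(x)
}

# Extract a sub-record for a 0-based half-open region; id is preserved.
sub_record <- function(rec, start, end) {
  stopifnot(start >= 0, end <= rec$length, start < end)
  seq_record(rec$id, substr(rec$residues, start + 1L, end),
             description = rec$description)
}

#' Region on a sequence
#'
#' A 0-based, half-open interval `[start, end)` on a named sequence.
#'
#' @param sequence_id Identifier of the referenced sequence.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param seq_length Optional length of the referenced sequence, used to
#'   validate `end <= seq_length`.
#' @return An object of class `region`.
#' @export
region <- function(sequence_id, start, end, seq_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid region [", start, ", ", end, ")")
  if (!is.null(seq_length) && end > seq_length)
    stop("region [", start, ", ", end, ") exceeds sequence length ", seq_length)
  structure(list(sequence_id = sequence_id, start = start, end = end),
            class = "region")
}

region_width <- function(r) r$end - r$start

#' Scoring scheme for protein alignment
#'
#' Substitution matrix plus affine gap penalties. A gap of length L is charged
#' `gap_open + gap_extend * (L - 1)`: the opening penalty covers the first gap
#' residue.
#'
#' @param matrix A matrix name known to Biostrings (e.g. `"BLOSUM62"`,
#'   `"BLOSUM45"`, `"PAM250"`), a path to a matrix in NCBI text format, or a
#'   symmetric integer matrix with single-letter dimnames including `X`.
#' @param gap_open Non-negative opening penalty (default 11).
#' @param gap_extend Non-negative extension penalty (default 1); must not
#'   exceed `gap_open`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L, gap_extend = 1L) {
  if (is.character(matrix) && length(matrix) == 1L) {
    name <- matrix
    if (file.exists(name)) {
      matrix <- read_score_matrix(name)
    } else {
      e <- new.env()
      ok <- tryCatch({
        utils::data(list = name, package = "Biostrings", envir = e)
        TRUE
      }, warning = function(w) FALSE, error = function(err) FALSE)
      if (!ok || !exists(name, envir = e))
        stop("unknown substitution matrix '", name, "'")
      matrix <- get(name, envir = e)
      storage.mode(matrix) <- "integer"
    }
  } else {
    name <- "custom"
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must be square with matching dimnames")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (!("X" %in% rownames(matrix)))
    stop("substitution matrix must contain an 'X' row")
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (gap_open < 0L || gap_extend < 0L || gap_extend > gap_open)
    stop("require 0 <= gap_extend <= gap_open")
  storage.mode(matrix) <- "integer"
  structure(list(matrix = matrix, matrix_name = name,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited matrix format used by NCBI (`#` comment
#' lines, a header row of single-letter column labels, then one labelled row
#' per residue).
#'
#' @param path Path to the matrix file.
#' @return An integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("matrix file '", path, "' is empty")
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  labs <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-1L]))
    if (anyNA(v) || length(v) != length(cols))
      stop("malformed matrix row in '", path, "'")
    v
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labs, cols)
  m
}

#' Search hit
#'
#' One local match between a query and a subject sequence, with matched
#' regions in full-sequence 0-based half-open coordinates, an E-value, a bit
#' score and the search layer that produced it (0 = first search from the
#' original query).
#'
#' @param query_id,subject_id Sequence identifiers.
#' @param query_region,subject_region [region()] objects on the respective
#'   full sequences.
#' @param evalue Non-negative E-value.
#' @param bitscore Bit score (may be `NA`).
#' @param layer Non-negative integer search layer.
#' @return An object of class `search_hit`.
#' @export
search_hit <- function(query_id, subject_id, query_region, subject_region,
                       evalue, bitscore = NA_real_, layer = 0L) {
  if (!inherits(query_region, "region") || !inherits(subject_region, "region"))
    stop("regions must be region objects")
  if (!is.numeric(evalue) || is.na(evalue) || evalue < 0)
    stop("evalue must be a nonnegative number")
  layer <- as.integer(layer)
  if (layer < 0L) stop("layer must be nonnegative")
  structure(list(query_id = query_id, subject_id = subject_id,
                 query_region = query_region, subject_region = subject_region,
                 evalue = evalue, bitscore = bitscore, layer = layer),
            class = "search_hit")
}

#' Search path
#'
#' A chain of hits from the original query through intermediate sequences to a
#' final-database subject. The path score is the arithmetic sum of the member
#' hits' E-values; layers increase strictly by 1 from 0 and no sequence id is
#' visited twice.
#'
#' @param hits Non-empty list of [search_hit()] objects.
#' @return An object of class `search_path` with fields `hits` and
#'   `path_score`.
#' @export
search_path <- function(hits) {
  if (!is.list(hits) || length(hits) == 0L)
    stop("a search path needs at least one hit")
  for (k in seq_along(hits)) {
    h <- hits[[k]]
    if (!inherits(h, "search_hit")) stop("hits must be search_hit objects")
    if (h$layer != k - 1L)
      stop("path layers must increase by 1 from 0")
    if (k > 1L && !identical(hits[[k - 1L]]$subject_id, h$query_id))
      stop("hit ", k, " does not chain from the previous subject")
  }
  ids <- c(hits[[1L]]$query_id,
           vapply(hits, function(h) h$subject_id, ""))
  if (anyDuplicated(ids))
    stop("search path revisits a sequence id (cycle)")
  structure(list(hits = hits,
                 path_score = sum(vapply(hits, function(h) h$evalue, 0))),
            class = "search_path")
}

path_ids <- function(p) {
  c(p$hits[[1L]]$query_id, vapply(p$hits, function(h) h$subject_id, ""))
}

#' @export
print.search_path <- function(x, ...) {
  cat(sprintf("<search_path %s (score %.3g)>\n",
              paste(path_ids(x), collapse = " -> "), x$path_score))
  invisible(x)
}

#' Pairwise gapped alignment
#'
#' Two equal-length gapped rows over a pair of sequences. `a_start`/`b_start`
#' give the 0-based full-sequence position of the first aligned residue of
#' each row, so ungapping a row reproduces a contiguous sub-sequence. No
#' column may be gap-gap.
#'
#' @param a_id,b_id Sequence identifiers.
#' @param a_start,b_start 0-based start offsets of the aligned regions.
#' @param a_row,b_row Equal-length gapped row strings (gap symbol `-`).
#' @param score Optional alignment score.
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(a_id, b_id, a_start, b_start, a_row, b_row,
                               score = NA_real_) {
  if (nchar(a_row) != nchar(b_row))
    stop("alignment rows must have equal length")
  if (nchar(a_row) > 0L) {
    ra <- strsplit(a_row, "")[[1L]]; rb <- strsplit(b_row, "")[[1L]]
    if (any(ra == "-" & rb == "-")) stop("gap-gap column in alignment")
  }
  structure(list(a_id = a_id, b_id = b_id,
                 a_start = as.integer(a_start), b_start = as.integer(b_start),
                 a_row = a_row, b_row = b_row, score = score),
            class = "pairwise_alignment")
}

empty_alignment <- function(a_id, b_id) {
  pairwise_alignment(a_id, b_id, 0L, 0L, "", "", score = 0)
}

is_empty_alignment <- function(aln) nchar(aln$a_row) == 0L

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment %s/%s: %d columns, %d matched>\n",
              x$a_id, x$b_id, nchar(x$a_row), aligned_region_length(x)))
  invisible(x)
}

#' Residue correspondence map
#'
#' A strictly monotone, injective partial map between residue positions of two
#' sequences, in full-sequence 0-based coordinates: the gap-free content of a
#' pairwise alignment. May be empty.
#'
#' @param source_id,target_id Sequence identifiers.
#' @param i,j Equal-length integer vectors of paired positions, strictly
#'   increasing in both.
#' @return An object of class `residue_map`.
#' @export
residue_map <- function(source_id, target_id, i = integer(), j = integer()) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j))
    stop("i and j must have equal length")
  if (length(i) > 0L) {
    if (any(i < 0L) || any(j < 0L)) stop("map indices must be nonnegative")
    if (any(diff(i) <= 0L) || any(diff(j) <= 0L))
      stop("residue map must be strictly increasing in both coordinates")
  }
  structure(list(source_id = source_id, target_id = target_id, i = i, j = j),
            class = "residue_map")
}

map_size <- function(m) length(m$i)

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("<residue_map %s -> %s: %d pairs>\n",
              x$source_id, x$target_id, map_size(x)))
  invisible(x)
}

#' Residue map of a pairwise alignment
#'
#' Extracts the matched (residue, residue) columns of an alignment as a
#' [residue_map()], lifting positions to full-sequence coordinates. The
#' offsets are the full-sequence start positions of the aligned sub-sequences
#' (non-zero when the aligned rows were extracted sub-regions); they are added
#' on top of the alignment's own `a_start`/`b_start`.
#'
#' @param aln A [pairwise_alignment()].
#' @param offset_a,offset_b Full-sequence start offsets of the sub-sequences
#'   the alignment was computed on (default 0).
#' @param len_a,len_b Optional full sequence lengths; if given, any lifted
#'   index at or beyond the length is a coordinate error.
#' @return A [residue_map()] from the `a` sequence to the `b` sequence.
#' @export
residue_map_from_alignment <- function(aln, offset_a = 0L, offset_b = 0L,
                                       len_a = NULL, len_b = NULL) {
  if (is_empty_alignment(aln))
    return(residue_map(aln$a_id, aln$b_id))
  ra <- strsplit(aln$a_row, "")[[1L]]
  rb <- strsplit(aln$b_row, "")[[1L]]
  pa <- cumsum(ra != "-") - 1L + aln$a_start + as.integer(offset_a)
  pb <- cumsum(rb != "-") - 1L + aln$b_start + as.integer(offset_b)
  keep <- ra != "-" & rb != "-"
  i <- pa[keep]; j <- pb[keep]
  if (!is.null(len_a) && length(i) && max(i) >= len_a)
    stop("coordinate error: offset pushes index beyond sequence '", aln$a_id, "'")
  if (!is.null(len_b) && length(j) && max(j) >= len_b)
    stop("coordinate error: offset pushes index beyond sequence '", aln$b_id, "'")
  residue_map(aln$a_id, aln$b_id, i, j)
}

#' Sequence database
#'
#' A named collection of [seq_record()] objects with optional SCOP-style
#' classification codes (sccs, e.g. `"a.1.1.1"`) for a subset of ids.
#'
#' @param records List of [seq_record()] objects with unique ids.
#' @param name Database name.
#' @param classification Optional named character vector mapping ids to sccs
#'   codes; names must be a subset of record ids.
#' @return An object of class `seq_database`.
#' @export
seq_database <- function(records, name = "db", classification = NULL) {
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  names(records) <- ids
  if (!is.null(classification)) {
    if (is.null(names(classification)) ||
        !all(names(classification) %in% ids))
      stop("classification must be named by record ids")
  }
  structure(list(name = name, records = records,
                 classification = classification),
            class = "seq_database")
}

#' @export
print.seq_database <- function(x, ...) {
  cat(sprintf("<seq_database %s: %d records%s>\n", x$name, length(x$records),
              if (is.null(x$classification)) "" else ", classified"))
  invisible(x)
}

#' @export
length.seq_database <- function(x) length(x$records)
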