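#' Hamming distance between two equal-length strings
#'
#' Counts mismatching positions; substitutions only, no indels. Any
#' position where either string carries an N counts as a mismatch, so an
#' N can never attest a match.
#'
#' @param a,b strings of equal length.
#' @return integer distance.
#' @examples
#' hamming("IMG", "ING")   # 1
#' hamming("ANGT", "ACGT") # 1
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  rn <- charToRaw("N")
  sum(ra != rb | ra == rn | rb == rn)
}

new_match_set <- function(query, m, complement_mode, count, positions) {
  structure(
    list(query = query, m = as.integer(m), k = nchar(query),
         complement_mode = complement_mode,
         occurrence_count = as.integer(count),
         positions = as.integer(positions)),
    class = "match_set"
  )
}

#' @export
print.match_set <- function(x, ...) {
  cat("match_set: query ", x$query, " (k=", x$k, ", m=", x$m, ", ",
      x$complement_mode, ")\n", sep = "")
  cat("  occurrences:", x$occurrence_count,
      " distinct positions:", length(x$positions), "\n")
  invisible(x)
}

check_match_args <- function(ref, k, m, complement_mode) {
  if (k < 1) stop("k must be >= 1")
  if (m < 0 || m >= k) stop("m must satisfy 0 <= m < k")
  if (k > max(ref$lengths))
    stop("k exceeds the longest contig; no window can exist")
  if (complement_mode == "dna" && ref$alphabet != "dna")
    stop("complement_mode 'dna' requires a DNA reference; ",
         "use 'forward_only' for raw alphabets")
}

#' Count occurrences of a k-mer within m substitutions
#'
#' Scans every window of the reference exhaustively. In `"dna"` mode the
#' occurrence count is the number of forward-strand windows within
#' Hamming distance m of the query plus the number within m of its
#' reverse complement; a palindromic window therefore counts twice, while
#' the position set holds each forward-strand start once. Windows
#' containing N never match, and a query containing N matches nothing.
#' `"forward_only"` mode compares characters literally with no
#' complement-strand term, for arbitrary alphabets.
#'
#' @param ref a [reference_sequence()].
#' @param query the k-mer to search for.
#' @param m maximum number of substitutions, `0 <= m < k`.
#' @param complement_mode `"dna"` (default) or `"forward_only"`.
#' @return A `match_set` with fields `occurrence_count` (with strand
#'   multiplicity) and `positions` (distinct forward-strand global
#'   0-based starts).
#' @examples
#' ref <- reference_sequence(c(toy = "......PING-PONG....."), alphabet = "raw")
#' count_matches(ref, "ING", m = 1, complement_mode = "forward_only")
#' @export
count_matches <- function(ref, query, m,
                          complement_mode = c("dna", "forward_only")) {
  stopifnot(inherits(ref, "reference_sequence"))
  complement_mode <- match.arg(complement_mode)
  query <- as.character(query)
  check_match_args(ref, nchar(query), m, complement_mode)
  if (complement_mode == "dna" && grepl("[^ACGTN]", query))
    stop("query contains characters outside {A,C,G,T,N}")
  res <- cpp_count_matches(unname(ref$seqs), query, as.integer(m),
                           complement_mode == "dna")
  new_match_set(query, m, complement_mode, res$count, res$positions)
}

#' Build a search index over a reference
#'
#' The index answers the same queries as [count_matches()] with identical
#' results, via pigeonhole seed hashing: a query within m mismatches of a
#' window must agree exactly with it on at least one of m+1 query chunks,
#' so hashed chunk lookups enumerate a candidate superset that is then
#' verified by Hamming distance.
#'
#' @param ref a [reference_sequence()].
#' @return An opaque `search_index` object.
#' @seealso [indexed_count_matches()]
#' @export
build_index <- function(ref) {
  stopifnot(inherits(ref, "reference_sequence"))
  structure(list(ref = ref), class = "search_index")
}

#' Query a search index
#'
#' Accepts one query or a batch of equal-length queries (batching shares
#' one seed-table construction). Results are identical to
#' [count_matches()] for every `(query, m)`.
#'
#' @param index a [build_index()] object.
#' @param query character vector of queries, all of the same length.
#' @param m maximum number of substitutions.
#' @param complement_mode `"dna"` or `"forward_only"`.
#' @return A `match_set` for a single query, otherwise a list of them.
#' @export
indexed_count_matches <- function(index, query, m,
                                  complement_mode = c("dna", "forward_only")) {
  stopifnot(inherits(index, "search_index"))
  complement_mode <- match.arg(complement_mode)
  ref <- index$ref
  query <- as.character(query)
  if (length(query) == 0) return(list())
  k <- nchar(query[1])
  if (any(nchar(query) != k))
    stop("all queries in one batch must share the same length")
  check_match_args(ref, k, m, complement_mode)
  if (complement_mode == "dna" && any(grepl("[^ACGTN]", query)))
    stop("query contains characters outside {A,C,G,T,N}")
  res <- cpp_indexed_matches(unname(ref$seqs), query, as.integer(m),
                             complement_mode == "dna")
  out <- lapply(seq_along(query), function(i) {
    new_match_set(query[i], m, complement_mode,
                  res[[i]]$count, res[[i]]$positions)
  })
  if (length(out) == 1) out[[1]] else out
}
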