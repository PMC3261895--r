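#' Default propagation threshold for a genome of length n
#'
#' Grows slowly with genome size (`max(8, ceiling(log2(n)))`, about 27
#' for a 100 Mb genome and 32 for 3 Gb), so that small frequency classes
#' are always computed exactly while large repeat classes are collapsed.
#'
#' @param x a [reference_sequence()] or a sequence length.
#' @return integer threshold.
#' @export
default_t <- function(x) {
  n <- if (inherits(x, "reference_sequence")) x$n else as.numeric(x)
  max(8L, as.integer(ceiling(log2(n))))
}

new_frequency_track <- function(values, k, m, t, contigs) {
  # decoded representatives of overflow bins can exceed integer range
  if (!is.integer(values)) values <- as.numeric(values)
  structure(
    list(values = values, k = as.integer(k), m = as.integer(m),
         t = t, contigs = contigs, n = length(values)),
    class = "frequency_track"
  )
}

#' Construct a frequency track from raw values
#'
#' Mainly useful for building small tracks by hand; [compute_frequency_track()]
#' is the normal entry point.
#'
#' @param values integer vector of per-position occurrence counts
#'   (0 = undefined position).
#' @param k,m,t track parameters (`t = Inf` marks an exact track).
#' @param contigs data.frame with columns `name` and `length`; lengths must
#'   sum to `length(values)`.
#' @return A `frequency_track`.
#' @export
frequency_track <- function(values, k, m, t = Inf, contigs) {
  stopifnot(is.data.frame(contigs), all(c("name", "length") %in% names(contigs)))
  if (sum(contigs$length) != length(values))
    stop("contig lengths must sum to length(values)")
  contigs$offset <- c(0L, cumsum(contigs$length))[seq_len(nrow(contigs))]
  new_frequency_track(values, k, m, t, contigs)
}

track_contig_table <- function(ref) {
  data.frame(name = ref$names, length = unname(ref$lengths),
             offset = unname(ref$offsets), stringsAsFactors = FALSE)
}

#' @export
print.frequency_track <- function(x, ...) {
  tlab <- if (is.infinite(x$t)) "exact" else x$t
  cat("frequency_track: n=", x$n, ", k=", x$k, ", m=", x$m, ", t=", tlab,
      "\n", sep = "")
  cat("  defined positions:", sum(x$values > 0L),
      " unique:", sum(x$values == 1L), "\n")
  invisible(x)
}

#' @export
print.mappability_track <- function(x, ...) {
  tlab <- if (is.infinite(x$t)) "exact" else x$t
  cat("mappability_track: n=", x$n, ", k=", x$k, ", m=", x$m, ", t=", tlab,
      "\n", sep = "")
  invisible(x)
}

#' Compute a k-mer frequency track (approximate or exact)
#'
#' For every position i hosting a valid window (k bases left in the
#' contig, no N), the frequency F\[i\] is the number of occurrences of the
#' k-mer starting at i in the reference and in its reverse complement,
#' counting as equivalent all k-mers within m substitutions.
#'
#' Positions are visited in ascending order. When a position is still
#' unset, its k-mer is matched against the whole reference; the
#' occurrence count is stored, and -- if the set P of distinct matching
#' start positions has at least `t` elements -- that count is also
#' propagated to every member of P (taking the maximum where a value is
#' already present, so that skipped positions are never underestimated).
#' Propagated positions are subsequently skipped, which is what makes the
#' computation fast on repetitive sequence. The result is exact wherever
#' the reported value is below `t`, exact at every unique position for
#' any `t`, exact everywhere when `m = 0`, and exact everywhere when the
#' approximation is disabled with `t = Inf`.
#'
#' @param ref a [reference_sequence()] (DNA alphabet).
#' @param k k-mer length in bp.
#' @param m maximum number of substitutions, `0 <= m < k`.
#' @param t propagation threshold (integer >= 2), or `Inf` to disable the
#'   approximation and compute exact frequencies. Defaults to
#'   [default_t()] of the genome length.
#' @return A `frequency_track` (values 0 at undefined positions).
#' @examples
#' ref <- reference_sequence(c(c1 = "ACGACGT"))
#' compute_frequency_track(ref, k = 3, m = 0, t = Inf)$values
#' @export
compute_frequency_track <- function(ref, k, m, t = default_t(ref)) {
  stopifnot(inherits(ref, "reference_sequence"))
  check_match_args(ref, k, m, "dna")
  if (ref$alphabet != "dna") stop("frequency tracks require a DNA reference")
  if (!is.infinite(t)) {
    if (!is.finite(t) || t < 2)
      stop("t must be >= 2 (t = 1 would propagate over unique positions); ",
           "use t = Inf to disable the approximation")
    t <- as.numeric(as.integer(t))
  }
  F <- cpp_frequency_track(unname(ref$seqs), as.integer(k), as.integer(m),
                           t, TRUE)
  new_frequency_track(F, k, m, t, track_contig_table(ref))
}

#' Compute the exact k-mer frequency track
#'
#' Equivalent to [compute_frequency_track()] with the approximation
#' disabled (`t = Inf`): every valid position is matched directly.
#'
#' @inheritParams compute_frequency_track
#' @return A `frequency_track` with exact values.
#' @export
exact_frequency_track <- function(ref, k, m) {
  compute_frequency_track(ref, k, m, t = Inf)
}

#' Exhaustive-scan frequencies (reference implementation)
#'
#' Computes frequencies by brute-force window scanning with no index and
#' no propagation, one full pass over the reference per queried position.
#' Slow by design; it serves as the independent oracle against which the
#' indexed engine and the propagation algorithm are validated.
#'
#' @inheritParams compute_frequency_track
#' @param positions integer vector of global 0-based positions to
#'   evaluate, or `NULL` for all positions.
#' @return If `positions` is `NULL`, a `frequency_track`; otherwise an
#'   integer vector of frequencies at the requested positions.
#' @export
brute_frequency_track <- function(ref, k, m, positions = NULL) {
  stopifnot(inherits(ref, "reference_sequence"))
  check_match_args(ref, k, m, "dna")
  full <- is.null(positions)
  if (full) positions <- seq.int(0L, ref$n - 1L)
  F <- cpp_brute_frequencies(unname(ref$seqs), as.integer(k), as.integer(m),
                             TRUE, as.integer(positions))
  if (full) new_frequency_track(F, k, m, Inf, track_contig_table(ref)) else F
}

#' Convert frequencies to mappabilities
#'
#' The mappability M\[i\] is 1/F\[i\] wherever the frequency is defined
#' (a value in (0, 1], with 1 marking a uniquely mappable position), and
#' 0 where F\[i\] = 0.
#'
#' @param track a `frequency_track`.
#' @return A `mappability_track` with numeric `values`.
#' @export
frequency_to_mappability <- function(track) {
  stopifnot(inherits(track, "frequency_track"))
  v <- ifelse(track$values > 0L, 1 / track$values, 0)
  structure(
    list(values = v, k = track$k, m = track$m, t = track$t,
         contigs = track$contigs, n = track$n),
    class = "mappability_track"
  )
}

#' Bin-migration matrix between an exact and an approximate track
#'
#' Both tracks are reduced to encoded frequency bins with the given
#' codec; entry (a, b) counts positions whose exact value encodes to bin
#' a and whose approximate value encodes to bin b. A perfect
#' approximation yields a diagonal matrix; off-diagonal mass in row a
#' shows how the approximation scatters the positions of exact bin a
#' into neighbouring bins.
#'
#' @param exact,approx `frequency_track`s over the same reference with
#'   the same k and m.
#' @param codec an [encoding_table()].
#' @return Integer matrix with one row/column per code; row sums equal
#'   exact bin occupancies.
#' @export
compare_bins <- function(exact, approx, codec = encoding_table()) {
  stopifnot(inherits(exact, "frequency_track"),
            inherits(approx, "frequency_track"))
  if (exact$k != approx$k || exact$m != approx$m || exact$n != approx$n)
    stop("tracks differ in k, m or length; bin migration is undefined")
  codes <- 0:(codec$code_count - 1L)
  ce <- factor(encode_frequency(exact$values, codec), levels = codes)
  ca <- factor(encode_frequency(approx$values, codec), levels = codes)
  mat <- table(exact = ce, approx = ca)
  unclass(as.matrix(mat))
}
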