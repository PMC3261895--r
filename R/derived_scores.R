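#' Paired-end library geometry
#'
#' Describes a sequencing library by its read length l and insert size d
#' (start-to-start distance between the two mate windows). The fragment
#' size standard deviation is taken as zero: all pairs are exactly d
#' apart.
#'
#' @param read_length read length l in bp (>= 1).
#' @param insert_size insert size d in bp (> read_length).
#' @return A `library_spec`.
#' @export
library_spec <- function(read_length, insert_size) {
  read_length <- as.integer(read_length)
  insert_size <- as.integer(insert_size)
  if (read_length < 1) stop("read_length must be >= 1")
  if (insert_size <= read_length) stop("insert_size must exceed read_length")
  structure(list(read_length = read_length, insert_size = insert_size,
                 size_sd = 0), class = "library_spec")
}

# contig id (row of track$contigs) per global position, NA if out of range
track_contig_of <- function(track, p) {
  out <- rep(NA_integer_, length(p))
  ok <- !is.na(p) & p >= 0 & p < track$n
  out[ok] <- findInterval(p[ok], track$contigs$offset)
  out
}

#' Pileup mappability of genomic positions
#'
#' A pileup column at position p can receive reads starting at any of
#' the l window positions p-l+1 .. p, so the mappability of the column
#' is the mean single-position mappability over the covering window
#' starts that are valid (same contig, frequency defined). Positions
#' within l-1 of a contig start simply average over the reduced valid
#' set; if no covering window is valid the pileup mappability is 0.
#'
#' @param track a `mappability_track` computed with k equal to the read
#'   length.
#' @param p integer vector of global 0-based positions.
#' @param read_length read length l; must equal the track's k.
#' @return Numeric vector of values in `[0, 1]`.
#' @export
pileup_mappability <- function(track, p, read_length = track$k) {
  stopifnot(inherits(track, "mappability_track"))
  if (read_length != track$k)
    stop("read_length (", read_length, ") must equal the track k (",
         track$k, "); recompute the track for this read length")
  l <- as.integer(read_length)
  p <- as.integer(p)
  if (any(p < 0) || any(p >= track$n)) stop("position out of range")
  cid <- track_contig_of(track, p)
  cstart <- track$contigs$offset[cid]
  vapply(seq_along(p), function(i) {
    starts <- max(cstart[i], p[i] - l + 1L):p[i]
    v <- track$values[starts + 1L]
    v <- v[v > 0]
    if (length(v) == 0) 0 else mean(v)
  }, numeric(1))
}

#' Paired-end mappability via the three-case rule
#'
#' The mate windows of a read covering position p start at p - d and
#' p + d. Writing u for the pileup mappability at p and v for the pileup
#' mappabilities at the available mates (a mate is unavailable when it
#' falls off the contig or on an undefined position), exactly three
#' cases arise: (1) u is at least as large as every available mate --
#' the pair information cannot help, return u; (2) u is smaller than
#' exactly one available mate -- return the average of u and that mate;
#' (3) u is smaller than both mates -- return the average of the two
#' mates. With no available mate the single-end value u is returned.
#'
#' @param track a `mappability_track` with k equal to the read length.
#' @param p integer vector of global 0-based positions.
#' @param lib a [library_spec()].
#' @return Numeric vector of values in `[0, 1]`, never below the
#'   single-end pileup mappability.
#' @export
paired_end_mappability <- function(track, p, lib) {
  stopifnot(inherits(track, "mappability_track"),
            inherits(lib, "library_spec"))
  d <- lib$insert_size
  p <- as.integer(p)
  u <- pileup_mappability(track, p, lib$read_length)
  cid <- track_contig_of(track, p)
  vapply(seq_along(p), function(i) {
    vs <- numeric(0)
    for (q in c(p[i] - d, p[i] + d)) {
      if (q < 0 || q >= track$n) next
      if (track_contig_of(track, q) != cid[i]) next
      if (track$values[q + 1L] == 0) next      # undefined mate position
      vs <- c(vs, pileup_mappability(track, q, lib$read_length))
    }
    if (length(vs) == 0) return(u[i])
    larger <- vs[vs > u[i]]
    if (length(larger) == 0) u[i]                        # case 1
    else if (length(larger) == 1) (u[i] + larger) / 2    # case 2
    else mean(vs)                                        # case 3
  }, numeric(1))
}

#' Fraction of non-unique positions completely rescued by pairing
#'
#' Among valid positions whose frequency exceeds 1 (the reads that are
#' not uniquely mappable on their own), counts those whose both mate
#' windows at distance d -- on the same contig -- are unique (frequency
#' exactly 1): for such a pair either end pins the fragment down, so the
#' position is rescued completely.
#'
#' @param track a `frequency_track`.
#' @param lib a [library_spec()].
#' @return Fraction in `[0, 1]`, or `NA` when the genome has no
#'   non-unique position.
#' @export
rescue_fraction <- function(track, lib) {
  stopifnot(inherits(track, "frequency_track"),
            inherits(lib, "library_spec"))
  stats <- rescue_stats(track, lib$insert_size)
  elig <- sum(stats$eligible)
  if (elig == 0) return(NA_real_)
  sum(stats$rescued) / elig
}

# per-contig eligible / rescued counts for one insert size
rescue_stats <- function(track, d) {
  nC <- nrow(track$contigs)
  eligible <- integer(nC)
  rescued <- integer(nC)
  for (i in seq_len(nC)) {
    off <- track$contigs$offset[i]
    len <- track$contigs$length[i]
    F <- track$values[(off + 1L):(off + len)]
    el <- F > 1
    eligible[i] <- sum(el)
    if (eligible[i] == 0) next
    pos <- which(el)                       # 1-based within contig
    lo <- pos - d
    hi <- pos + d
    ok <- lo >= 1L & hi <= len
    ok[ok] <- F[lo[ok]] == 1 & F[hi[ok]] == 1
    rescued[i] <- sum(ok)
  }
  data.frame(contig = track$contigs$name, eligible = eligible,
             rescued = rescued, stringsAsFactors = FALSE)
}

#' Rescue-fraction sweep over insert sizes
#'
#' @param track a `frequency_track`.
#' @param insert_sizes integer vector of insert sizes d to evaluate.
#' @return data.frame with one row per (contig, d): columns `contig`,
#'   `d`, `eligible_positions`, `rescued`, `fraction` (`NA` when a
#'   contig has no eligible position).
#' @export
rescue_sweep <- function(track, insert_sizes) {
  stopifnot(inherits(track, "frequency_track"))
  out <- lapply(as.integer(insert_sizes), function(d) {
    st <- rescue_stats(track, d)
    data.frame(contig = st$contig, d = d,
               eligible_positions = st$eligible, rescued = st$rescued,
               fraction = ifelse(st$eligible > 0,
                                 st$rescued / st$eligible, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Proper length of a sequence
#'
#' The shortest word length l such that a string of length l is expected
#' to occur about once in a random sequence of length n over an alphabet
#' of size s, i.e. the smallest l with `s^l >= n`. Read lengths above
#' the proper length would make a random genome uniquely mappable almost
#' everywhere; real genomes deviate because of their repeat content.
#'
#' @param n sequence length (>= 1).
#' @param s alphabet size (default 4).
#' @return Integer vector of proper lengths.
#' @examples
#' proper_length(3107677273)  # 16 (human-genome scale)
#' @export
proper_length <- function(n, s = 4) {
  if (any(n < 1) || s < 2) stop("need n >= 1 and s >= 2")
  vapply(as.numeric(n), function(ni) {
    l <- 0L
    v <- 1
    while (v < ni) {
      v <- v * s
      l <- l + 1L
    }
    l
  }, integer(1))
}
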