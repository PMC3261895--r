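# Shared fixture builders. All randomness is seeded at call sites.

random_ref <- function(n, seed, n_contigs = 1L) {
  set.seed(seed)
  lens <- if (n_contigs == 1L) n else {
    cuts <- sort(sample.int(n - 1L, n_contigs - 1L))
    diff(c(0L, cuts, n))
  }
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("c", seq_along(seqs))
  reference_sequence(seqs)
}

# enumeration oracle for exact m = 0 frequencies: count every k-mer by
# sorting/grouping, then F[i] = count(w_i) + count(rc(w_i)); windows with
# N (and contig tails) get 0.  Independent of the matching engine.
enumeration_frequencies_m0 <- function(ref, k) {
  F <- integer(ref$n)
  # gather all valid windows genome-wide first
  all_w <- character(0)
  per_contig <- list()
  for (ci in seq_along(ref$names)) {
    s <- ref$seqs[[ci]]
    L <- nchar(s)
    if (L < k) {
      per_contig[[ci]] <- list(w = character(0), rw = character(0),
                               valid = logical(0))
      next
    }
    w <- substring(s, 1:(L - k + 1L), k:L)
    rs <- mappable::reverse_complement(s)
    # window i (1-based) of s corresponds to rc at window L-k+2-i of rs
    rw <- substring(rs, (L - k + 1L):1, L:k)
    valid <- !grepl("N", w, fixed = TRUE)
    per_contig[[ci]] <- list(w = w, rw = rw, valid = valid)
    all_w <- c(all_w, w[valid])
  }
  u <- unique(all_w)
  cnt <- tabulate(match(all_w, u), nbins = length(u))
  for (ci in seq_along(ref$names)) {
    pc <- per_contig[[ci]]
    if (length(pc$w) == 0) next
    fwd <- cnt[match(pc$w, u)]
    rev <- cnt[match(pc$rw, u)]
    fwd[is.na(fwd)] <- 0L
    rev[is.na(rev)] <- 0L
    f <- fwd + rev
    f[!pc$valid] <- 0L
    off <- ref$offsets[ci]
    F[(off + 1L):(off + length(f))] <- f
  }
  F
}

# genome made of literal pieces laid end to end on one contig;
# returns ref plus the 0-based interval of each named piece
composite_genome <- function(pieces) {
  seq <- paste(pieces, collapse = "")
  offs <- c(0L, cumsum(nchar(pieces)))
  iv <- data.frame(piece = names(pieces),
                   start = offs[seq_along(pieces)],
                   end = offs[-1L], stringsAsFactors = FALSE)
  list(ref = reference_sequence(c(chr1 = seq)), intervals = iv)
}

# independent R transcription of the propagation algorithm, driven by the
# exhaustive count_matches scan: ascending traversal, skip non-zero, store
# the occurrence count, and when |P| >= t propagate it over P with the
# max rule.  Used to validate the C++ implementation wholesale.
reference_propagation <- function(ref, k, m, t) {
  F <- integer(ref$n)
  for (ci in seq_along(ref$names)) {
    s <- ref$seqs[[ci]]
    off <- ref$offsets[ci]
    L <- nchar(s)
    if (L < k) next
    for (p in 1:(L - k + 1L)) {
      g <- off + p
      if (F[g] != 0L) next
      w <- substr(s, p, p + k - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      ms <- count_matches(ref, w, m)
      F[g] <- ms$occurrence_count
      if (is.finite(t) && length(ms$positions) >= t) {
        for (j in ms$positions + 1L) {
          F[j] <- if (F[j] == 0L) ms$occurrence_count else
            max(F[j], ms$occurrence_count)
        }
      }
    }
  }
  F
}

expect_match_set_equal <- function(a, b) {
  expect_identical(a$occurrence_count, b$occurrence_count)
  expect_identical(a$positions, b$positions)
}
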