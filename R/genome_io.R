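#' Build a reference sequence object
#'
#' A reference sequence is an ordered set of named contigs laid out on a
#' single global 0-based coordinate axis. In `"dna"` mode sequences are
#' normalized to the `{A,C,G,T,N}` alphabet: lowercase (soft-masked) bases
#' are folded to uppercase and every IUPAC ambiguity code other than
#' A/C/G/T is collapsed to N, the conservative convention under which an
#' ambiguous base can never support a match. `"raw"` mode accepts arbitrary
#' printable characters and exists for forward-only matching on toy
#' alphabets.
#'
#' @param seqs named character vector, one element per contig.
#' @param alphabet `"dna"` (default) or `"raw"`.
#' @return An object of class `reference_sequence` with fields `names`,
#'   `seqs`, `lengths`, `offsets` (global 0-based contig starts), `n`
#'   (total length) and `alphabet`.
#' @examples
#' ref <- reference_sequence(c(chr1 = "ACGTACGT", chr2 = "GGGCCC"))
#' ref$n
#' @export
reference_sequence <- function(seqs, alphabet = c("dna", "raw")) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) == 0) stop("a reference needs at least one contig")
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stop("contig names must be non-empty")
  if (anyDuplicated(nm)) stop("contig names must be unique")
  seqs <- as.character(seqs)
  if (alphabet == "dna") {
    seqs <- normalize_dna(seqs)
  }
  lens <- nchar(seqs)
  offs <- c(0L, cumsum(lens))[seq_along(seqs)]
  structure(
    list(names = nm, seqs = stats::setNames(seqs, nm),
         lengths = stats::setNames(as.integer(lens), nm),
         offsets = stats::setNames(as.integer(offs), nm),
         n = sum(as.integer(lens)), alphabet = alphabet),
    class = "reference_sequence"
  )
}

# uppercase, U and ambiguity codes -> N; reject anything non-IUPAC
normalize_dna <- function(seqs) {
  seqs <- toupper(seqs)
  seqs <- chartr("URYSWKMBDHV", "NNNNNNNNNNN", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1], regexpr("[^ACGTN]", seqs[bad][1]))
    stop("invalid character '", ch, "' in DNA sequence")
  }
  seqs
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat("reference_sequence:", length(x$names), "contig(s),", x$n, "bp,",
      x$alphabet, "alphabet\n")
  for (i in seq_along(x$names)) {
    cat("  ", x$names[i], " (", x$lengths[i], " bp, offset ",
        x$offsets[i], ")\n", sep = "")
  }
  invisible(x)
}

#' Read a reference genome from a FASTA file
#'
#' Contigs are loaded in file order, names are truncated at the first
#' whitespace, and sequences are normalized as in [reference_sequence()]
#' (lowercase folded, non-ACGT IUPAC codes collapsed to N).
#'
#' @param path path to a (multi-)FASTA file, wrapped or unwrapped.
#' @return A [reference_sequence()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  first <- which(nzchar(trimws(head_lines)))[1]
  if (is.na(first) || !startsWith(head_lines[first], ">"))
    stop("malformed FASTA: line ", if (is.na(first)) 1L else first,
         " is not a '>' header")
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("malformed FASTA: no records in ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0)) {
    stop("malformed FASTA: empty record '",
         names(seqs)[nchar(seqs) == 0][1], "'")
  }
  reference_sequence(seqs, alphabet = "dna")
}

#' Write a reference genome to FASTA
#'
#' @param ref a [reference_sequence()].
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path, width = 60L) {
  stopifnot(inherits(ref, "reference_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ref$names)) {
    writeLines(paste0(">", ref$names[i]), con)
    writeLines(wrap_string(ref$seqs[[i]], width), con)
  }
  invisible(path)
}

wrap_string <- function(s, width) {
  n <- nchar(s)
  if (n == 0) return(character(0))
  starts <- seq.int(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement, reversed; N maps to N. Errors on any
#' character outside `{A,C,G,T,N}`.
#'
#' @param s character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("ACGGN")  # "NCCGT"
#' @export
reverse_complement <- function(s) {
  vapply(as.character(s), cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Map global positions to (contig, offset) pairs
#'
#' Positions are 0-based; offsets are 0-based within the contig.
#'
#' @param ref a [reference_sequence()].
#' @param g integer vector of global positions, `0 <= g < ref$n`.
#' @return data.frame with columns `contig` and `offset`.
#' @export
global_to_local <- function(ref, g) {
  stopifnot(inherits(ref, "reference_sequence"))
  g <- as.integer(g)
  if (any(is.na(g)) || any(g < 0L) || any(g >= ref$n))
    stop("global position out of range [0, ", ref$n, ")")
  idx <- findInterval(g, ref$offsets)
  data.frame(contig = ref$names[idx], offset = g - ref$offsets[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map (contig, offset) pairs to global positions
#'
#' @param ref a [reference_sequence()].
#' @param contig character vector of contig names.
#' @param offset integer vector of 0-based offsets within each contig.
#' @return integer vector of global 0-based positions.
#' @export
local_to_global <- function(ref, contig, offset) {
  stopifnot(inherits(ref, "reference_sequence"))
  idx <- match(contig, ref$names)
  if (any(is.na(idx))) stop("unknown contig: ", contig[is.na(idx)][1])
  offset <- as.integer(offset)
  if (any(offset < 0L) || any(offset >= ref$lengths[idx]))
    stop("offset out of contig range")
  as.integer(ref$offsets[idx] + offset)
}
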