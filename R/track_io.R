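#' Reduced-precision frequency encoding table
#'
#' Frequencies are stored as one printable ASCII character per position
#' ('!' through '~', 94 codes). Code 0 marks an undefined position
#' (frequency 0); codes 1..`exact_max` encode those frequencies exactly;
#' the remaining codes carve the range `(exact_max, 2^32]` into
#' geometrically growing intervals, with the last code acting as an
#' overflow catch-all. Low frequencies -- the ones for which precision
#' matters, since mappability = 1/F -- are therefore lossless, while a
#' large frequency is recovered as the geometric midpoint of its bin,
#' which bounds the multiplicative error and barely perturbs the
#' (already tiny) mappability.
#'
#' @param exact_max largest exactly encoded frequency (default 60).
#' @param code_count total number of codes (default 94, the printable
#'   ASCII range).
#' @return An `encoding_table` with vectors `lo`, `hi`, `rep` indexed by
#'   code + 1, the growth factor `g`, and the defining constants.
#' @export
encoding_table <- function(exact_max = 60L, code_count = 94L) {
  exact_max <- as.integer(exact_max)
  code_count <- as.integer(code_count)
  if (code_count > 94L) stop("at most 94 printable single-character codes")
  if (exact_max < 1L || code_count < exact_max + 3L)
    stop("need at least two range codes above exact_max")
  top <- 2^32
  n_part <- code_count - exact_max - 2L  # codes partitioning (exact_max, 2^32]
  g <- (top / exact_max)^(1 / n_part)
  codes <- 0:(code_count - 1L)
  hi <- numeric(code_count)
  lo <- numeric(code_count)
  hi[1] <- 0; lo[1] <- 0                      # code 0: undefined
  hi[2:(exact_max + 1L)] <- 1:exact_max       # exact codes
  lo[2:(exact_max + 1L)] <- 1:exact_max
  rng <- (exact_max + 1L):(code_count - 2L)   # geometric range codes
  hi[rng + 1L] <- round(exact_max * g^(seq_along(rng)))
  hi[code_count - 1L] <- top                  # force exact top of last range
  lo[rng + 1L] <- hi[rng] + 1
  hi[code_count] <- Inf                       # overflow catch-all
  lo[code_count] <- top + 1
  if (any(diff(hi[-code_count]) <= 0))
    stop("degenerate encoding table: bins not strictly increasing")
  rep <- numeric(code_count)
  rep[1] <- 0
  rep[2:(exact_max + 1L)] <- 1:exact_max
  rep[rng + 1L] <- round(sqrt(lo[rng + 1L] * hi[rng + 1L]))
  rep[code_count] <- 2 * top
  structure(
    list(code_count = code_count, exact_max = exact_max, g = g,
         codes = codes, lo = lo, hi = hi, rep = rep),
    class = "encoding_table"
  )
}

#' Encode frequencies as reduced-precision codes
#'
#' @param F non-negative numeric vector of frequencies.
#' @param codec an [encoding_table()].
#' @return Integer vector of codes in `0:(code_count-1)`; monotone
#'   non-decreasing in F.
#' @export
encode_frequency <- function(F, codec = encoding_table()) {
  stopifnot(inherits(codec, "encoding_table"))
  F <- as.numeric(F)
  if (any(is.na(F)) || any(F < 0)) stop("frequencies must be non-negative")
  out <- integer(length(F))
  ex <- F > 0 & F <= codec$exact_max
  out[ex] <- as.integer(F[ex])
  big <- F > codec$exact_max
  if (any(big)) {
    # boundaries of the range codes, in code order
    rng_hi <- codec$hi[(codec$exact_max + 2L):codec$code_count]
    out[big] <- codec$exact_max + findInterval(F[big] - 0.5, rng_hi) + 1L
  }
  out
}

#' Decode codes to representative frequencies
#'
#' Exact codes decode to themselves; a range code decodes to the
#' (rounded) geometric midpoint of its bin; code 0 decodes to 0.
#'
#' @param code integer vector of codes.
#' @param codec an [encoding_table()].
#' @return Numeric vector of representative frequencies, one per code;
#'   re-encoding a representative returns its code.
#' @export
decode_frequency <- function(code, codec = encoding_table()) {
  stopifnot(inherits(codec, "encoding_table"))
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L) || any(code >= codec$code_count))
    stop("code out of range")
  codec$rep[code + 1L]
}

track_t_label <- function(t) if (is.infinite(t)) "exact" else format(t)
track_t_parse <- function(s) if (identical(s, "exact")) Inf else as.numeric(s)

#' Write a frequency track as pseudo-multi-FASTA
#'
#' The file starts with a `~`-prefixed preamble carrying the track
#' parameters (k, m, t), the codec constants and the contig table,
#' followed by one `>name` header per contig and 60-character wrapped
#' lines in which each base's frequency code is stored as the printable
#' character `chr(33 + code)`. Files are self-describing: the reader
#' reconstructs the codec from the preamble.
#'
#' @param track a `frequency_track`.
#' @param path output path.
#' @param codec an [encoding_table()].
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, codec = encoding_table()) {
  stopifnot(inherits(track, "frequency_track"))
  if (nrow(track$contigs) == 0) stop("track has no contigs")
  codes <- encode_frequency(track$values, codec)
  con <- file(path, "wb")
  on.exit(close(con))
  pre <- c("~gemap-track 1",
           paste("~k", track$k),
           paste("~m", track$m),
           paste("~t", track_t_label(track$t)),
           paste("~codec", codec$code_count, codec$exact_max),
           "~linebases 60",
           paste("~contig", track$contigs$name, track$contigs$length))
  writeLines(pre, con)
  for (i in seq_len(nrow(track$contigs))) {
    off <- track$contigs$offset[i]
    len <- track$contigs$length[i]
    writeLines(paste0(">", track$contigs$name[i]), con)
    chars <- rawToChar(as.raw(33L + codes[(off + 1L):(off + len)]))
    writeLines(wrap_string(chars, 60L), con)
  }
  invisible(path)
}

#' Read a track written by [write_track()]
#'
#' @param path track file path.
#' @return A `frequency_track` whose `values` are the decoded
#'   representative frequencies, with the raw codes in attribute
#'   `"codes"` and the codec in attribute `"codec"`.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # the preamble is the leading run of ~ lines; afterwards records are
  # parsed structurally from the contig table, because encoded body lines
  # may begin with any printable character (including '>' and '~')
  npre <- 0L
  while (npre < length(lines) && startsWith(lines[npre + 1L], "~"))
    npre <- npre + 1L
  meta <- lines[seq_len(npre)]
  if (length(meta) == 0 || !startsWith(meta[1], "~gemap-track"))
    stop("not a gemap track file: ", path)
  get1 <- function(key) {
    hit <- meta[startsWith(meta, paste0("~", key, " "))]
    if (length(hit) == 0) stop("track preamble is missing '", key, "'")
    strsplit(sub(paste0("^~", key, " "), "", hit[1]), " ")[[1]]
  }
  k <- as.integer(get1("k"))
  m <- as.integer(get1("m"))
  t <- track_t_parse(get1("t"))
  cc <- as.integer(get1("codec"))
  lb <- as.integer(get1("linebases"))
  codec <- encoding_table(exact_max = cc[2], code_count = cc[1])
  ctg <- meta[startsWith(meta, "~contig ")]
  parts <- strsplit(sub("^~contig ", "", ctg), " ")
  contigs <- data.frame(name = vapply(parts, `[`, "", 1),
                        length = as.integer(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  pos <- npre + 1L
  codes <- integer(0)
  for (i in seq_len(nrow(contigs))) {
    if (pos > length(lines) ||
        !identical(lines[pos], paste0(">", contigs$name[i])))
      stop("record order differs from contig table")
    nlin <- ceiling(contigs$length[i] / lb)
    if (pos + nlin > length(lines)) stop("truncated track body")
    block <- lines[pos + seq_len(nlin)]
    codes <- c(codes, utf8ToInt(paste(block, collapse = "")) - 33L)
    pos <- pos + nlin + 1L
  }
  if (length(codes) != sum(contigs$length))
    stop("track body length does not match the contig table")
  tr <- frequency_track(decode_frequency(codes, codec), k, m, t, contigs)
  attr(tr, "codes") <- codes
  attr(tr, "codec") <- codec
  tr
}

track_index_path <- function(path) paste0(path, ".idx")

#' Build a byte-offset index for fast region retrieval
#'
#' Writes a faidx-style sidecar (`<path>.idx`) recording, per contig, the
#' byte offset of its first encoded character plus the line geometry, so
#' [query_region()] can seek directly to a slice without reading the file.
#'
#' @param path track file path.
#' @return The index data.frame, invisibly.
#' @export
build_track_index <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  npre <- 0L
  while (npre < length(lines) && startsWith(lines[npre + 1L], "~"))
    npre <- npre + 1L
  meta <- lines[seq_len(npre)]
  lb <- as.integer(sub("^~linebases ", "",
                       meta[startsWith(meta, "~linebases ")]))
  ctg <- meta[startsWith(meta, "~contig ")]
  parts <- strsplit(sub("^~contig ", "", ctg), " ")
  idx <- data.frame(name = vapply(parts, `[`, "", 1),
                    length = as.integer(vapply(parts, `[`, "", 2)),
                    offset = NA_real_, linebases = lb, linewidth = lb + 1L,
                    stringsAsFactors = FALSE)
  # walk records structurally (body lines may start with any printable char)
  byte <- sum(nchar(meta, type = "bytes") + 1L)
  for (i in seq_len(nrow(idx))) {
    byte <- byte + nchar(idx$name[i], type = "bytes") + 2L  # ">name\n"
    idx$offset[i] <- byte
    nlin <- ceiling(idx$length[i] / lb)
    byte <- byte + idx$length[i] + nlin  # codes plus one newline per line
  }
  utils::write.table(idx, track_index_path(path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(idx)
}

read_track_preamble <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  meta <- character(0)
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0 || !startsWith(ln, "~")) break
    meta <- c(meta, ln)
  }
  cc <- strsplit(sub("^~codec ", "", meta[startsWith(meta, "~codec ")]), " ")[[1]]
  list(k = as.integer(sub("^~k ", "", meta[startsWith(meta, "~k ")])),
       m = as.integer(sub("^~m ", "", meta[startsWith(meta, "~m ")])),
       t = track_t_parse(sub("^~t ", "", meta[startsWith(meta, "~t ")])),
       codec = encoding_table(exact_max = as.integer(cc[2]),
                              code_count = as.integer(cc[1])))
}

#' Retrieve a region from an indexed track file
#'
#' Seeks into the encoded body using the sidecar index (built on demand)
#' and decodes only the requested `[start, end)` slice; results agree
#' with slicing a full [read_track()].
#'
#' @param path track file path.
#' @param contig contig name.
#' @param start,end 0-based half-open interval within the contig.
#' @return data.frame with columns `contig`, `pos`, `code`, `frequency`
#'   (decoded representative) and `mappability`.
#' @export
query_region <- function(path, contig, start, end) {
  if (start < 0 || end <= start) stop("need 0 <= start < end")
  ipath <- track_index_path(path)
  idx <- if (file.exists(ipath)) {
    utils::read.table(ipath, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    build_track_index(path)
  }
  row <- idx[idx$name == contig, ]
  if (nrow(row) != 1) stop("unknown contig '", contig, "' in track index")
  if (end > row$length) stop("interval exceeds contig length ", row$length)
  pre <- read_track_preamble(path)
  byte_of <- function(p) row$offset + p + (p %/% row$linebases) *
    (row$linewidth - row$linebases)
  b0 <- byte_of(start)
  b1 <- byte_of(end - 1)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, where = b0)
  raw <- readChar(con, nchars = b1 - b0 + 1, useBytes = TRUE)
  raw <- gsub("\n", "", raw, fixed = TRUE)
  codes <- utf8ToInt(raw) - 33L
  freq <- decode_frequency(codes, pre$codec)
  data.frame(contig = contig, pos = seq.int(start, end - 1L),
             code = codes, frequency = freq,
             mappability = ifelse(freq > 0, 1 / freq, 0),
             stringsAsFactors = FALSE)
}

#' Export a mappability track to BedGraph
#'
#' Emits 0-based half-open intervals with adjacent equal-value runs
#' merged; undefined positions are written with value 0, so the exported
#' intervals tile every contig completely.
#'
#' @param track a `mappability_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "mappability_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(track$contigs))) {
    off <- track$contigs$offset[i]
    len <- track$contigs$length[i]
    v <- track$values[(off + 1L):(off + len)]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%.10g", track$contigs$name[i],
                       starts, ends, r$values), con)
  }
  invisible(path)
}
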