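#' Project transcript annotation onto per-gene exon unions
#'
#' Collapses all transcripts of a gene into the union of their exons on
#' genomic coordinates, so that each exon fragment is counted once
#' regardless of how many isoforms share it. Accepts a GTF/GFF3 file
#' (attributes `gene_id` and `gene_type`/`gene_biotype` are used), a
#' BED12 file (block structure; class defaults to "unknown"), a
#' `GRanges` of exons, or a data.frame of exon intervals with columns
#' `gene_id`, `class`, `contig`, `start`, `end` (0-based half-open).
#'
#' @param annotation path or object as described above.
#' @param ref optional [reference_sequence()]; intervals on contigs
#'   absent from `ref` are dropped with a warning.
#' @return A `gene_models` data.frame with one row per union interval:
#'   columns `gene_id`, `class`, `contig`, `start`, `end` (0-based
#'   half-open), `strand`; intervals per gene are disjoint and sorted.
#' @export
project_exons <- function(annotation, ref = NULL) {
  df <- annotation_to_exons(annotation)
  if (nrow(df) == 0) stop("annotation contains no exons")
  if (!is.null(ref)) {
    bad <- !(df$contig %in% ref$names)
    if (any(bad)) {
      warning("dropping ", sum(bad), " exon(s) on contigs absent from the ",
              "reference: ", paste(unique(df$contig[bad]), collapse = ", "))
      df <- df[!bad, , drop = FALSE]
      if (nrow(df) == 0) stop("no exons left after contig filtering")
    }
  }
  merged <- lapply(split(df, df$gene_id), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    data.frame(gene_id = g$gene_id[1], class = g$class[1],
               contig = g$contig[1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               strand = g$strand[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

annotation_to_exons <- function(annotation) {
  if (is.data.frame(annotation)) {
    need <- c("gene_id", "contig", "start", "end")
    if (!all(need %in% names(annotation)))
      stop("exon data.frame needs columns ", paste(need, collapse = ", "))
    df <- as.data.frame(annotation, stringsAsFactors = FALSE)
    if (is.null(df$class)) df$class <- "unknown"
    if (is.null(df$strand)) df$strand <- "+"
    return(df[, c("gene_id", "class", "contig", "start", "end", "strand")])
  }
  if (methods::is(annotation, "GRanges")) {
    return(granges_to_exons(annotation))
  }
  if (is.character(annotation) && length(annotation) == 1) {
    if (!file.exists(annotation)) stop("annotation file not found: ", annotation)
    if (grepl("\\.bed$", annotation, ignore.case = TRUE)) {
      gr <- rtracklayer::import(annotation, format = "bed")
      bl <- rtracklayer::blocks(gr)
      ex <- unlist(bl)
      gene <- rep(gr$name, S4Vectors::elementNROWS(bl))
      df <- data.frame(gene_id = gene, class = "unknown",
                       contig = as.character(GenomicRanges::seqnames(ex)),
                       start = GenomicRanges::start(ex) - 1L,
                       end = GenomicRanges::end(ex),
                       strand = as.character(GenomicRanges::strand(ex)),
                       stringsAsFactors = FALSE)
      return(df)
    }
    gr <- rtracklayer::import(annotation)
    return(granges_to_exons(gr))
  }
  stop("unsupported annotation input")
}

granges_to_exons <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type)) gr <- gr[as.character(mc$type) == "exon"]
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id)) stop("annotation lacks gene_id attributes")
  cls <- mc$gene_type
  if (is.null(cls)) cls <- mc$gene_biotype
  if (is.null(cls)) cls <- mc$biotype
  if (is.null(cls)) cls <- rep("unknown", length(gr))
  cls <- as.character(cls)
  cls[is.na(cls)] <- "unknown"
  data.frame(gene_id = as.character(mc$gene_id), class = cls,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Exon-union lengths per gene
#'
#' @param genes a `gene_models` data.frame from [project_exons()].
#' @return Named integer vector of total union lengths L.
#' @export
gene_lengths <- function(genes) {
  v <- tapply(genes$end - genes$start, genes$gene_id, sum)
  stats::setNames(as.integer(v), names(v))
}

# per-row slices of track values over [start, end)
track_slice <- function(track, contig, start, end) {
  i <- match(contig, track$contigs$name)
  if (is.na(i)) stop("contig '", contig, "' absent from the track")
  if (start < 0 || end > track$contigs$length[i]) stop("interval out of range")
  off <- track$contigs$offset[i]
  track$values[(off + start + 1L):(off + end)]
}

#' Uniquely mappable exonic length per gene
#'
#' Counts the window-start positions inside each gene's exon union whose
#' frequency is exactly 1, i.e. the portion of the feature that can
#' contribute uniquely mapping reads at the track's (k, m). Window
#' starts near an exon's 3' boundary use the genomic k-mer, which may
#' run into the intron.
#'
#' @param genes a `gene_models` data.frame.
#' @param track a `frequency_track`.
#' @return Named integer vector U, `0 <= U <= L` per gene.
#' @export
unique_exonic_length <- function(genes, track) {
  stopifnot(inherits(track, "frequency_track"))
  per_row <- vapply(seq_len(nrow(genes)), function(r) {
    sum(track_slice(track, genes$contig[r], genes$start[r],
                    genes$end[r]) == 1)
  }, numeric(1))
  v <- tapply(per_row, genes$gene_id, sum)
  stats::setNames(as.integer(v), names(v))
}

#' Gene expression with and without mappability correction
#'
#' RPKM divides the unique-read count by total exonic length L; when
#' multi-mapping reads are discarded, only the uniquely mappable part of
#' a gene can collect reads, so RPKM underestimates repetitive genes.
#' RPKUM normalizes by the uniquely mappable exonic length U instead:
#' `rpkm = 1e9 * c / (L * N)` and `rpkum = 1e9 * c / (U * N)` for count
#' c and N total mapped reads; `rpkum` is `NA` where U = 0.
#'
#' @param genes a `gene_models` data.frame.
#' @param counts per-gene unique-read counts: a named numeric vector, a
#'   two-column data.frame (`gene_id`, `count`), or a TSV path of the
#'   same layout. Genes missing from `counts` get count 0 with a warning.
#' @param total_mapped total mapped reads N (>= 1).
#' @param track a `frequency_track` with the mapping parameters used for
#'   the counts.
#' @return data.frame with columns `gene_id`, `class`, `length`,
#'   `unique_length`, `count`, `rpkm`, `rpkum`.
#' @export
compute_expression <- function(genes, counts, total_mapped, track) {
  if (total_mapped < 1) stop("total_mapped must be >= 1")
  counts <- as_gene_counts(counts)
  L <- gene_lengths(genes)
  U <- unique_exonic_length(genes, track)
  ids <- names(L)
  cls <- genes$class[match(ids, genes$gene_id)]
  cnt <- counts[ids]
  if (any(is.na(cnt))) {
    warning("no counts for gene(s): ",
            paste(ids[is.na(cnt)], collapse = ", "), "; using 0")
    cnt[is.na(cnt)] <- 0
  }
  if (any(cnt < 0)) stop("read counts must be non-negative")
  rpkm <- 1e9 * cnt / (L * total_mapped)
  rpkum <- ifelse(U > 0, 1e9 * cnt / (U * total_mapped), NA_real_)
  data.frame(gene_id = ids, class = cls, length = unname(L),
             unique_length = unname(U), count = unname(cnt),
             rpkm = unname(rpkm), rpkum = unname(rpkum),
             stringsAsFactors = FALSE, row.names = NULL)
}

as_gene_counts <- function(counts) {
  if (is.character(counts) && length(counts) == 1) {
    counts <- utils::read.table(counts, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  }
  if (is.data.frame(counts)) {
    if (!all(c("gene_id", "count") %in% names(counts)))
      stop("counts need columns gene_id and count")
    return(stats::setNames(as.numeric(counts$count), counts$gene_id))
  }
  if (is.numeric(counts) && !is.null(names(counts))) return(counts)
  stop("counts must be a named vector, data.frame or TSV path")
}

#' Count read starts falling in each gene's exon union
#'
#' A convenience counter for BED-like read positions; alignment itself
#' is out of scope, so mapped read starts are taken as input.
#'
#' @param genes a `gene_models` data.frame.
#' @param reads a BED path (columns chrom, start, ...; 0-based) or a
#'   data.frame with columns `contig` and `start`.
#' @return Named numeric vector of per-gene counts.
#' @export
count_reads_bed <- function(genes, reads) {
  if (is.character(reads) && length(reads) == 1) {
    bed <- utils::read.table(reads, sep = "\t", stringsAsFactors = FALSE)
    reads <- data.frame(contig = bed[[1]], start = bed[[2]],
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("contig", "start") %in% names(reads)))
  by_ctg <- lapply(split(as.numeric(reads$start), reads$contig), sort)
  per_row <- vapply(seq_len(nrow(genes)), function(r) {
    s <- by_ctg[[genes$contig[r]]]
    if (is.null(s)) return(0)
    sum(findInterval(genes$end[r] - 0.5, s) -
          findInterval(genes$start[r] - 0.5, s))
  }, numeric(1))
  v <- tapply(per_row, genes$gene_id, sum)
  stats::setNames(as.numeric(v), names(v))
}

#' Per-class mappability profile of a projected transcriptome
#'
#' For each gene class, reports the fraction of exon-union positions
#' that are uniquely mappable (F = 1), ambiguous (F > 1) and undefined
#' (F = 0), plus a full histogram of positions over encoded frequency
#' bins -- the representation in which, e.g., a clustered multi-copy
#' RNA family shows up as a concentrated occupancy peak around its copy
#' number.
#'
#' @param genes a `gene_models` data.frame.
#' @param track a `frequency_track`.
#' @param codec an [encoding_table()].
#' @return A list with `summary` (data.frame: class, n_positions,
#'   frac_unique, frac_ambiguous, frac_undefined) and `histogram`
#'   (matrix class x code of position counts).
#' @export
class_profile <- function(genes, track, codec = encoding_table()) {
  stopifnot(inherits(track, "frequency_track"))
  classes <- sort(unique(genes$class))
  codes <- 0:(codec$code_count - 1L)
  hist <- matrix(0L, nrow = length(classes), ncol = length(codes),
                 dimnames = list(classes, as.character(codes)))
  summ <- data.frame(class = classes, n_positions = 0L,
                     frac_unique = NA_real_, frac_ambiguous = NA_real_,
                     frac_undefined = NA_real_, stringsAsFactors = FALSE)
  for (ci in seq_along(classes)) {
    rows <- which(genes$class == classes[ci])
    F <- unlist(lapply(rows, function(r) {
      track_slice(track, genes$contig[r], genes$start[r], genes$end[r])
    }))
    summ$n_positions[ci] <- length(F)
    summ$frac_unique[ci] <- mean(F == 1)
    summ$frac_ambiguous[ci] <- mean(F > 1)
    summ$frac_undefined[ci] <- mean(F == 0)
    cc <- encode_frequency(F, codec)
    tab <- tabulate(cc + 1L, nbins = codec$code_count)
    hist[ci, ] <- tab
  }
  list(summary = summ, histogram = hist)
}

#' Write gene models as GTF
#'
#' One transcript per gene; each union interval becomes an exon row with
#' `gene_id`, `transcript_id` and `gene_type` attributes.
#'
#' @param genes a `gene_models` data.frame.
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "mappable") {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_type "%s";',
                   genes$gene_id, genes$gene_id, genes$class)
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   genes$contig, source, genes$start + 1L, genes$end,
                   genes$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}
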