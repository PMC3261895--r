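test_that("exon projection unions transcript exons per gene", {
  ex <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB"),
    class = "protein_coding", contig = "chr1",
    start = c(100L, 100L, 150L, 180L),
    end = c(200L, 200L, 250L, 400L),
    strand = "+", stringsAsFactors = FALSE)
  gm <- project_exons(ex)
  a <- gm[gm$gene_id == "gA", ]
  expect_identical(nrow(a), 1L)
  expect_identical(c(a$start, a$end), c(100L, 250L))
  expect_identical(sum(gm$end - gm$start), 150L + 220L)
  # overlapping genes stay separate models
  expect_identical(nrow(gm[gm$gene_id == "gB", ]), 1L)
})

test_that("GTF round-trip through the writer preserves unions", {
  g <- generate_genome(8000, list(repeat_spec(150, 3, 0)), seed = 23)
  genes <- generate_annotation(g, seed = 24)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genes, gtf)
  back <- project_exons(gtf, ref = g$ref)
  expect_identical(back$gene_id, genes$gene_id)
  expect_identical(back$start, genes$start)
  expect_identical(back$end, genes$end)
  expect_identical(back$class, genes$class)
})

test_that("unknown contigs are dropped with a warning; empty errors", {
  ex <- data.frame(gene_id = c("g1", "g2"), class = "x",
                   contig = c("chr1", "chrUn"),
                   start = c(0L, 0L), end = c(50L, 50L),
                   strand = "+", stringsAsFactors = FALSE)
  ref <- reference_sequence(c(chr1 = strrep("ACGT", 30)))
  expect_warning(gm <- project_exons(ex, ref = ref), "chrUn")
  expect_identical(gm$gene_id, "g1")
  expect_error(suppressWarnings(
    project_exons(ex[2, ], ref = ref)), "no exons")
})

test_that("unique exonic length counts F == 1 positions", {
  k <- 25L
  set.seed(131)
  unit <- paste(sample(c("A", "C", "G", "T"), 300 + k - 1L, TRUE),
                collapse = "")
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  # second copy carries the same (unit + k-1 margin) so that every window
  # starting inside the gene's repeat half is non-unique
  cg <- composite_genome(c(a = bg(2000), r1 = unit, b = bg(2000),
                           r2 = unit, c = bg(2000)))
  tr <- exact_frequency_track(cg$ref, k, 0)
  iv <- cg$intervals
  gene <- data.frame(gene_id = "g1", class = "pc", contig = "chr1",
                     start = iv$start[iv$piece == "r1"] - 300L,
                     end = iv$start[iv$piece == "r1"] + 300L,
                     strand = "+", stringsAsFactors = FALSE)
  gm <- project_exons(gene)
  U <- unique_exonic_length(gm, tr)
  L <- gene_lengths(gm)
  expect_identical(unname(L), 600L)
  expect_identical(unname(U), 300L)  # exactly the background half
  # fully unique gene
  gene2 <- data.frame(gene_id = "g2", class = "pc", contig = "chr1",
                      start = 100L, end = 700L, strand = "+",
                      stringsAsFactors = FALSE)
  expect_identical(unname(unique_exonic_length(project_exons(gene2), tr)),
                   600L)
})

test_that("a gene inside an N gap has zero unique length", {
  g <- generate_genome(3000, gaps = list(count = 1, length = 400), seed = 43)
  tr <- exact_frequency_track(g$ref, 20, 0)
  gap <- g$gaps[1, ]
  gene <- project_exons(data.frame(
    gene_id = "gN", class = "x", contig = gap$contig,
    start = gap$start + 10L, end = gap$end - 30L, strand = "+",
    stringsAsFactors = FALSE))
  expect_identical(unname(unique_exonic_length(gene, tr)), 0L)
})

test_that("RPKM and RPKUM follow their definitions", {
  tr <- frequency_track(rep(1L, 1000), k = 10, m = 0, t = Inf,
                        contigs = data.frame(name = "chr1", length = 1000L))
  gm <- project_exons(data.frame(gene_id = "g1", class = "pc",
                                 contig = "chr1", start = 0L, end = 1000L,
                                 strand = "+", stringsAsFactors = FALSE))
  ex <- compute_expression(gm, c(g1 = 100), 1e6, tr)
  expect_equal(ex$rpkm, 100)
  expect_equal(ex$rpkum, 100)
  # missing counts warn and default to zero
  expect_warning(ex0 <- compute_expression(gm, c(other = 5), 1e6, tr),
                 "no counts")
  expect_identical(ex0$count, 0)
  # U = 0 gives NA RPKUM but defined RPKM
  tr0 <- frequency_track(rep(2L, 1000), k = 10, m = 0, t = Inf,
                         contigs = data.frame(name = "chr1", length = 1000L))
  exNA <- compute_expression(gm, c(g1 = 10), 1e6, tr0)
  expect_true(is.na(exNA$rpkum))
  expect_false(is.na(exNA$rpkm))
})

test_that("half-unique gene recovers full expression under RPKUM", {
  # two equally expressed genes of equal length; gene B half unique:
  # with multi-mappers discarded B collects half the reads, so its RPKM
  # halves while RPKUM restores equality
  F <- rep(1L, 4000)
  F[2001:2500] <- 2L  # second half of gene B
  tr <- frequency_track(F, k = 10, m = 0, t = Inf,
                        contigs = data.frame(name = "chr1", length = 4000L))
  gm <- project_exons(data.frame(
    gene_id = c("gA", "gB"), class = "pc", contig = "chr1",
    start = c(500L, 1500L), end = c(1500L, 2500L), strand = "+",
    stringsAsFactors = FALSE))
  ex <- compute_expression(gm, c(gA = 200, gB = 100), 1e6, tr)
  ex <- ex[order(ex$gene_id), ]
  expect_equal(ex$rpkm[2], ex$rpkm[1] / 2)
  expect_equal(ex$rpkum[2], ex$rpkum[1])
  # rpkum/rpkm = L/U identity wherever both are defined
  expect_equal(ex$rpkum / ex$rpkm, ex$length / ex$unique_length)
})

test_that("read-start counting matches interval membership", {
  gm <- project_exons(data.frame(
    gene_id = c("g1", "g2"), class = "pc", contig = "chr1",
    start = c(100L, 300L), end = c(200L, 320L), strand = "+",
    stringsAsFactors = FALSE))
  reads <- data.frame(contig = "chr1",
                      start = c(99, 100, 150, 199, 200, 310, 319, 320))
  cnt <- count_reads_bed(gm, reads)
  expect_identical(cnt[["g1"]], 3)  # 100, 150, 199
  expect_identical(cnt[["g2"]], 2)  # 310, 319
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tr\t0\t+", reads$start, reads$start + 36),
             bed)
  expect_identical(count_reads_bed(gm, bed), cnt)
})

test_that("class profiles separate unique and clustered repeat classes", {
  g <- generate_genome(12000, list(repeat_spec(250, 10, 0)), seed = 53)
  genes <- generate_annotation(
    g, classes = data.frame(class = c("protein_coding", "rRNA"),
                            n = c(4L, 3L), placement = c("background", "repeat"),
                            stringsAsFactors = FALSE), seed = 54)
  tr <- exact_frequency_track(g$ref, 30, 0)
  prof <- class_profile(genes, tr)
  s <- prof$summary
  pc <- s[s$class == "protein_coding", ]
  rr <- s[s$class == "rRNA", ]
  expect_gt(pc$frac_unique, 0.95)
  expect_lt(rr$frac_unique, 0.5)
  # fractions conserve mass
  expect_equal(s$frac_unique + s$frac_ambiguous + s$frac_undefined,
               rep(1, nrow(s)))
  # the 10-copy cluster concentrates occupancy around the copy-number bin
  h <- prof$histogram["rRNA", ]
  peak <- sum(h[as.character(9:12)])
  expect_gt(peak / sum(h), 0.5)
})
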