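test_that("exact frequencies match hand/enumeration values", {
  ref <- reference_sequence(c(c1 = "ACGACGT"))
  tr <- exact_frequency_track(ref, k = 3, m = 0)
  # ACG: 2 forward + rc CGT once = 3; CGA, GAC unique; CGT symmetric with ACG;
  # the last two positions cannot host a 3-mer
  expect_identical(tr$values, c(3L, 1L, 1L, 3L, 3L, 0L, 0L))
  expect_identical(tr$values, enumeration_frequencies_m0(ref, 3))

  refA <- reference_sequence(c(c1 = "AAAAAA"))
  expect_identical(exact_frequency_track(refA, 3, 0)$values,
                   c(4L, 4L, 4L, 4L, 0L, 0L))
})

test_that("every valid position has F >= 1 and invalid positions stay 0", {
  g <- generate_genome(3000, list(repeat_spec(60, 4, 1)),
                       gaps = list(count = 2, length = 40), seed = 5)
  tr <- exact_frequency_track(g$ref, k = 12, m = 1)
  s <- g$ref$seqs[[1]]
  win_has_n <- vapply(1:(nchar(s) - 11L), function(i)
    grepl("N", substr(s, i, i + 11L), fixed = TRUE), logical(1))
  valid <- c(!win_has_n, rep(FALSE, 11L))
  expect_true(all(tr$values[valid] >= 1L))
  expect_true(all(tr$values[!valid] == 0L))
})

test_that("approximation is exact at m = 0 for any t", {
  for (seed in 1:3) {
    ref <- random_ref(2500, seed = 200 + seed)
    ex <- exact_frequency_track(ref, k = 8, m = 0)
    for (t in c(2, 5, 16)) {
      ap <- compute_frequency_track(ref, k = 8, m = 0, t = t)
      expect_identical(ap$values, ex$values)
    }
    expect_identical(ex$values, enumeration_frequencies_m0(ref, 8))
  }
})

test_that("disabling t gives exact frequencies for m > 0", {
  g <- generate_genome(1500, list(repeat_spec(40, 5, 2)), seed = 31)
  tr <- compute_frequency_track(g$ref, k = 20, m = 2, t = Inf)
  oracle <- brute_frequency_track(g$ref, k = 20, m = 2)
  expect_identical(tr$values, oracle$values)
})

test_that("t below 2 is rejected", {
  ref <- random_ref(200, seed = 1)
  expect_error(compute_frequency_track(ref, 5, 1, t = 1), "t must be >= 2")
  expect_error(compute_frequency_track(ref, 5, 1, t = 0), "t must be >= 2")
})

test_that("unique positions survive the approximation unchanged", {
  g <- generate_genome(4000, list(repeat_spec(50, 8, 2),
                                  repeat_spec(30, 3, 0)), seed = 77)
  ex <- exact_frequency_track(g$ref, k = 24, m = 2)
  for (t in c(2, 4, 8)) {
    ap <- compute_frequency_track(g$ref, k = 24, m = 2, t = t)
    expect_identical(which(ap$values == 1L), which(ex$values == 1L))
    # sub-threshold reported values are exact
    sub <- ap$values > 0L & ap$values < t
    expect_identical(ap$values[sub], ex$values[sub])
  }
})

test_that("propagation matches an independent transcription of the algorithm", {
  # small genomes with planted repeats and a gap, checked against a pure-R
  # ascending-order propagation driven by the exhaustive scanner; exercises
  # the skip rule, the |P| >= t threshold and the max rule together
  for (seed in 1:3) {
    g <- generate_genome(450, list(repeat_spec(25, 3, 1)),
                         gaps = list(count = 1, length = 15),
                         seed = 300 + seed)
    for (t in c(2, 3, 8)) {
      got <- compute_frequency_track(g$ref, k = 8, m = 1, t = t)
      expect_identical(got$values, reference_propagation(g$ref, 8, 1, t))
    }
  }
})

test_that("planted repeat families are recovered at their copy number", {
  g <- generate_genome(6000, list(repeat_spec(40, 12, 2)), seed = 13)
  ex <- exact_frequency_track(g$ref, k = 40, m = 2)
  starts <- g$truth$start + g$ref$offsets[g$truth$contig]
  expect_true(all(ex$values[starts + 1L] >= 12L))
  ap <- compute_frequency_track(g$ref, k = 40, m = 2, t = 4)
  expect_true(all(ap$values[starts + 1L] >= 12L))
  # background away from any copy stays unique at k = 40
  covered <- unlist(lapply(seq_len(nrow(g$truth)), function(i)
    (g$truth$start[i] - 39L):(g$truth$end[i] - 1L)))
  bg <- setdiff(0:(g$ref$n - 40L), covered)
  expect_true(all(ex$values[bg + 1L] == 1L))
})

test_that("track computation is deterministic", {
  g <- generate_genome(2000, list(repeat_spec(35, 6, 1)), seed = 9)
  a <- compute_frequency_track(g$ref, 18, 1, t = 4)
  b <- compute_frequency_track(g$ref, 18, 1, t = 4)
  expect_identical(a$values, b$values)
})

test_that("frequency to mappability is the guarded reciprocal", {
  tr <- frequency_track(c(1L, 2L, 4L, 0L), k = 2, m = 0,
                        contigs = data.frame(name = "c1", length = 4L))
  mt <- frequency_to_mappability(tr)
  expect_equal(mt$values, c(1, 0.5, 0.25, 0))
  ref <- reference_sequence(c(c1 = "ACGACGT"))
  mt2 <- frequency_to_mappability(exact_frequency_track(ref, 3, 0))
  expect_equal(mt2$values, c(1/3, 1, 1, 1/3, 1/3, 0, 0))
})

test_that("bin migration is diagonal when the approximation is exact", {
  g <- generate_genome(2500, list(repeat_spec(45, 7, 2)), seed = 55)
  ex <- exact_frequency_track(g$ref, 22, 2)
  # t disabled: identical tracks, diagonal matrix
  mig <- compare_bins(ex, compute_frequency_track(g$ref, 22, 2, t = Inf))
  expect_identical(sum(mig) , sum(diag(mig)))
  # m = 0: diagonal for any t
  ex0 <- exact_frequency_track(g$ref, 22, 0)
  ap0 <- compute_frequency_track(g$ref, 22, 0, t = 3)
  mig0 <- compare_bins(ex0, ap0)
  expect_identical(sum(mig0), sum(diag(mig0)))
  # row sums are the exact bin occupancies
  codec <- encoding_table()
  occ <- tabulate(encode_frequency(ex$values, codec) + 1L,
                  nbins = codec$code_count)
  ap <- compute_frequency_track(g$ref, 22, 2, t = 3)
  mig2 <- compare_bins(ex, ap)
  expect_identical(unname(rowSums(mig2)), as.numeric(occ))
  expect_error(compare_bins(ex, ap0), "differ in k, m")
})

test_that("exact tracks are monotone in m at fixed positions", {
  ref <- random_ref(1200, seed = 91)
  f0 <- exact_frequency_track(ref, 10, 0)$values
  f1 <- exact_frequency_track(ref, 10, 1)$values
  f2 <- exact_frequency_track(ref, 10, 2)$values
  valid <- f0 > 0
  expect_true(all(f1[valid] >= f0[valid]))
  expect_true(all(f2[valid] >= f1[valid]))
})
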