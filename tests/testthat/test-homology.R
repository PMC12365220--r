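test_that("longest common substring handles identity and disjoint alphabets", {
  r <- longest_common_substring("ACGT", "ACGT")
  expect_equal(r$length, 4L)
  expect_equal(c(r$pos_a, r$pos_b), c(0L, 0L))
  expect_equal(longest_common_substring("AAAA", "TTTT")$length, 0L)
  expect_error(longest_common_substring("", "ACGT"), "non-empty")
})

test_that("LCS and MEMs agree with brute-force DP oracles on random pairs", {
  set.seed(42)
  for (i in 1:60) {
    a <- rand_dna(sample(10:120, 1))
    b <- rand_dna(sample(10:120, 1))
    lcs <- longest_common_substring(a, b)
    expect_equal(lcs$length, lcs_oracle(a, b))
    if (lcs$length > 0)
      expect_identical(substr(a, lcs$pos_a + 1, lcs$pos_a + lcs$length),
                       substr(b, lcs$pos_b + 1, lcs$pos_b + lcs$length))
    ml <- sample(1:4, 1)
    got <- .sorted_segments(maximal_exact_matches(a, b, ml))
    exp <- .sorted_segments(mem_oracle(a, b, ml))
    expect_equal(got, exp)
  }
})

test_that("hand-enumerated MEM example and self-identity", {
  mem <- maximal_exact_matches("ACGTTT", "TTTACG", 3)
  expect_equal(nrow(mem), 2L)
  strings <- sort(substring("ACGTTT", mem$pos_a + 1, mem$pos_a + mem$length))
  expect_identical(strings, c("ACG", "TTT"))
  self <- maximal_exact_matches(strrep("ACGTAGCCTG", 1), strrep("ACGTAGCCTG", 1), 1)
  expect_true(any(self$length == 10))
})

test_that("dot plot equals exhaustive k-mer comparison", {
  d <- dotplot_matches("ACGTACGT", "ACGT", k = 4)
  expect_equal(d[, c("pos_a", "pos_b")],
               data.frame(pos_a = c(0L, 4L), pos_b = c(0L, 0L)))
  expect_equal(dotplot_matches("ACGTACGT", "ACGTACGT", k = 8)$pos_a, 0L)
  expect_equal(nrow(dotplot_matches("AAAA", "CCCC", k = 2)), 0L)
  expect_error(dotplot_matches("ACGT", "ACGT", k = 9), "k must")
  set.seed(7)
  for (i in 1:25) {
    a <- rand_dna(60); b <- rand_dna(60); k <- sample(2:6, 1)
    got <- dotplot_matches(a, b, k)
    exp <- dotplot_oracle(a, b, k)
    expect_equal(.sorted_segments(got[, c("pos_a", "pos_b")]),
                 .sorted_segments(exp))
  }
  # both-strand mode flags reverse-complement matches at forward coordinates
  a <- "AACCGGTTAA"
  b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  d2 <- dotplot_matches(a, b, k = 10, strand_mode = "both")
  expect_true(any(d2$strand == "-" & d2$pos_a == 0 & d2$pos_b == 0))
})

test_that("operations are symmetric under argument swap", {
  set.seed(99)
  for (i in 1:10) {
    a <- rand_dna(80); b <- rand_dna(80)
    expect_equal(longest_common_substring(a, b)$length,
                 longest_common_substring(b, a)$length)
    mab <- .sorted_segments(maximal_exact_matches(a, b, 2))
    mba <- maximal_exact_matches(b, a, 2)
    mba <- .sorted_segments(data.frame(pos_a = mba$pos_b, pos_b = mba$pos_a,
                                       length = mba$length))
    expect_equal(mab, mba)
  }
})

test_that("homology report ties its pieces together", {
  set.seed(5)
  a <- rand_dna(150); b <- rand_dna(150)
  rep <- homology_report(a, b, k = 4, min_len = 1)
  expect_equal(max(rep$mem_histogram$length_bp), rep$lcs$length)
  expect_equal(sum(rep$mem_histogram$count), nrow(maximal_exact_matches(a, b, 1)))
  # dotplot at k is the k-window expansion of MEMs of length >= k
  mem <- maximal_exact_matches(a, b, 4)
  expansion <- do.call(rbind, lapply(seq_len(nrow(mem)), function(i) {
    off <- 0:(mem$length[i] - 4)
    data.frame(pos_a = mem$pos_a[i] + off, pos_b = mem$pos_b[i] + off)
  }))
  expect_equal(.sorted_segments(rep$dotplot[, c("pos_a", "pos_b")]),
               .sorted_segments(expansion))
  # writers emit 1-based coordinates
  dp <- tempfile(); hs <- tempfile()
  write_dotplot_tsv(rep$dotplot, dp)
  write_mem_histogram_tsv(rep, hs)
  dtab <- read.delim(dp)
  expect_equal(dtab$pos_a_1based, rep$dotplot$pos_a + 1L)
  expect_equal(read.delim(hs)$count, rep$mem_histogram$count)
})
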