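usage <- codon_usage_mouse()
map20 <- allowed_codons(usage, 0.2)
map_opt <- suppressWarnings(allowed_codons(usage, 1))  # most-abundant only

test_that("motif scanning finds palindromes, reverse-only hits and absences", {
  ms <- motif_set(c(EcoRI = "GAATTC", asym = "GGATCA"))
  seq <- paste0("TTTT", "GAATTC", "TTTT")
  hits <- motif_scan(seq, ms)
  ecori <- hits[hits$motif == "EcoRI", ]
  expect_equal(nrow(ecori), 2L)            # palindrome: once per strand
  expect_equal(unique(ecori$pos), 4L)      # same locus
  expect_setequal(ecori$strand, c("+", "-"))
  # non-palindromic motif present only as its reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("GGATCA")))
  hits2 <- motif_scan(paste0("AAAA", rc, "AAAA"), ms)
  expect_equal(hits2$motif, "asym")
  expect_equal(hits2$strand, "-")
  expect_equal(nrow(motif_scan("ACACACACAC", ms)), 0L)
})

test_that("a forced single-residue target and determinism contracts hold", {
  r <- diversify(diversification_task("M", allowed = map20, budget = 5))
  expect_identical(r$output$seq, "ATG")
  expect_identical(r$fscore_vs_reference$log10_f, -Inf)
  pr <- make_random_protein(60, seed = 2)
  ref <- back_translate(pr, map_opt)$seq
  t1 <- diversification_task(pr, ref, allowed = map20, seed = 9, budget = 20000)
  r1 <- diversify(t1)
  r2 <- diversify(t1)
  expect_identical(r1$output$seq, r2$output$seq)
  expect_identical(r1$fscore_vs_reference$log10_f, r2$fscore_vs_reference$log10_f)
})

test_that("diversification conserves the protein and satisfies constraints", {
  motifs <- motif_set(restriction_sites()[1:6])
  set.seed(123)
  for (i in 1:25) {
    pr <- make_random_protein(sample(20:80, 1))
    bias <- sample(c(0, 0.1, 0.2), 1)
    map <- allowed_codons(usage, bias)
    ref <- if (i %% 2 == 0) back_translate(pr, map_opt)$seq else ""
    r <- diversify(diversification_task(pr, ref, allowed = map,
                                        forbidden = motifs, seed = i,
                                        budget = 2000))
    expect_identical(translate_cds(r$output)$seq, pr$seq)
    codons <- substring(r$output$seq, seq(1, nchar(r$output$seq), 3),
                        seq(3, nchar(r$output$seq), 3))
    expect_true(all(mapply(function(cod, aa) cod %in% map[[aa]], codons,
                           strsplit(pr$seq, "")[[1]])))
    expect_equal(nrow(motif_scan(r$output$seq, motifs)), 0L)
    if (nzchar(ref)) {
      junction <- paste0(substr(ref, nchar(ref) - 6, nchar(ref)), r$output$seq)
      expect_equal(nrow(motif_scan(junction, motifs)), 0L)
      expect_equal(r$max_identical_bp,
                   longest_common_substring(r$output$seq, ref)$length)
    }
  }
})

test_that("terminal stop codons are copied verbatim and kept out of the search", {
  cds <- back_translate(protein_sequence("MGKLVDQ*"), map_opt)
  r <- diversify(diversification_task(cds, allowed = map20, budget = 100))
  expect_true(endsWith(r$output$seq, "TAA"))
  expect_identical(translate_cds(r$output)$seq, "MGKLVDQ")
  expect_true(translate_cds(r$output)$has_stop)
})

test_that("the search scores at least as well as the abundance-greedy baseline", {
  set.seed(77)
  p <- energy_params()
  for (i in 1:5) {
    pr <- make_random_protein(80)
    # reference: an independently sampled usage-weighted CDS of the protein
    frac <- attr(allowed_codons(usage, 0), "fractions")
    ref <- paste(vapply(strsplit(pr$seq, "")[[1]], function(a) {
      f <- frac[[a]]; names(f)[sample.int(length(f), 1, prob = f)]
    }, character(1)), collapse = "")
    baseline <- back_translate(pr, map_opt)
    r <- diversify(diversification_task(pr, ref, allowed = map20,
                                        seed = i, budget = 30000))
    f_base <- pair_f(ref, baseline, p)$log10_f
    expect_lte(r$fscore_vs_reference$log10_f, f_base)
    expect_lt(r$fscore_vs_reference$log10_f, f_base)  # strictly better here
  }
})

test_that("unavoidable forbidden motifs raise an error naming the motif", {
  # lysine-only protein at a bias forcing AAG codons: AA dimers are everywhere
  expect_error(
    diversify(diversification_task("KKKK",
                                   allowed = suppressWarnings(allowed_codons(usage, 0.7)),
                                   forbidden = motif_set(c(poisoned = "AAGAAG")),
                                   budget = 10)),
    "poisoned")
})

test_that("a two-stage chain equals two manual runs with extended reference", {
  pr <- make_random_protein(40, seed = 4)
  ref <- back_translate(pr, map_opt)$seq
  mk <- function(seed) diversification_task(pr, allowed = map20, seed = seed,
                                            budget = 5000)
  ch <- diversify_chain(list(mk(11), mk(12)), shared_reference = ref)
  m1 <- diversify(diversification_task(pr, ref, allowed = map20, seed = 11,
                                       budget = 5000))
  m2 <- diversify(diversification_task(pr, paste0(ref, m1$output$seq),
                                       allowed = map20, seed = 12,
                                       budget = 5000))
  expect_identical(ch$results[[1]]$output$seq, m1$output$seq)
  expect_identical(ch$results[[2]]$output$seq, m2$output$seq)
  expect_equal(dim(ch$max_identical_bp), c(3L, 3L))
  expect_equal(ch$max_identical_bp["reference", "output1"],
               longest_common_substring(ref, m1$output$seq)$length)
  # error propagation from a poisoned stage
  expect_error(
    diversify_chain(list(
      diversification_task("KKKK", allowed = suppressWarnings(allowed_codons(usage, 0.7)),
                           forbidden = motif_set(c(bad = "AAGAAG")), budget = 5),
      mk(13)), shared_reference = ref),
    "bad")
})
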