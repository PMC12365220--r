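A5 <- "ACTCAGCGCTGCCTCAGTCC"   # synapsin-promoter-side anchor stand-in
A3 <- "GGACTGTTGGGCACTGACAG"   # WPRE-side anchor stand-in

test_that("insert extraction keeps exact sandwiches and drops the rest", {
  anch <- anchor_pair(A5, A3)
  reads <- c(paste0(A5, "ACGT", A3),
             paste0("TTGG", A5, "GGCCA", A3, "AATT"),
             paste0(A5, "ACGT"),                      # anchor3 missing
             "GGGGTTTTCCCCAAAAGGGGTTTT")
  ins <- extract_inserts(reads, anch)
  expect_identical(as.character(ins), c("ACGT", "GGCCA"))
  expect_equal(unname(attr(ins, "counts")), c(4L, 2L, 2L))
  # orientation normalization: a reverse-complemented read still yields its insert
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(A5, "TTGCAA", A3))))
  expect_identical(as.character(extract_inserts(rc, anch)), "TTGCAA")
})

test_that("anchor mismatches are tolerated up to the Hamming budget", {
  mut <- paste0(sub("^A", "T", A5), "ACGT", A3)
  expect_length(extract_inserts(mut, anchor_pair(A5, A3, 0)), 0L)
  expect_identical(as.character(extract_inserts(mut, anchor_pair(A5, A3, 1))),
                   "ACGT")
})

test_that("grouping counts identical inserts deterministically", {
  g <- group_inserts(c("AA", "AA", "AT"))
  expect_equal(g$insert, c("AA", "AT"))
  expect_equal(g$count, c(2L, 1L))
  expect_equal(nrow(group_inserts(character(0))), 0L)
  set.seed(2)
  ins <- sample(c("AAA", "CCC", "GGG"), 5000, replace = TRUE)
  expect_equal(sum(group_inserts(ins)$count), 5000L)
})

test_that("group calling letters donor/acceptor states and discards errors", {
  sites <- discriminating_sites("AAAA", "TTTT")
  expect_equal(sites$positions, 0:3)
  expect_identical(call_group(list(insert = "AATT", count = 1), sites)$calls,
                   c("C", "C", "Y", "Y"))
  expect_identical(call_group(list(insert = "AAAA", count = 1), sites)$calls,
                   rep("C", 4))
  bad <- call_group(list(insert = "AAGA", count = 1), sites)
  expect_identical(bad$status, "discard")
  expect_identical(bad$reason, "error")
  short <- call_group(list(insert = "AAAAAA", count = 1), sites)
  expect_identical(short$reason, "length")
  expect_error(discriminating_sites("AAAA", "AAAA"), "identical")
  expect_error(discriminating_sites("AAAA", "AAAAA"), "equal length")
})

test_that("the profile is the hand-computed weighted average", {
  sites <- discriminating_sites("AAAA", "TTTT")
  groups <- group_inserts(c(rep("AAAA", 3), "AATT"))
  prof <- recombination_profile(groups, sites)
  expect_equal(prof$profile$frac_acceptor, c(0, 0, 0.25, 0.25))
  expect_equal(prof$profile$n_valid, rep(4L, 4))
  # all-donor pool: flat zero profile, slope ~ 0
  flat <- recombination_profile(group_inserts(rep("AAAA", 10)), sites)
  expect_equal(flat$profile$frac_acceptor, rep(0, 4))
  expect_equal(flat$fit$slope, 0)
})

test_that("the simulator honors rho, seeds and class bookkeeping", {
  pair <- make_homolog_pair(60, 0.9, seed = 21)
  anch <- anchor_pair(A5, A3)
  cfg0 <- chimera_sim_config(pair$a$seq, pair$b$seq, linker = "GGTTCCAA",
                             n_reads = 200, rho = 0, anchors = anch, seed = 5)
  sim0 <- simulate_chimeric_reads(cfg0)
  expect_true(all(sim0$truth$class == "full"))
  full_len <- nchar(pair$a$seq) * 2 + 8
  ins0 <- extract_inserts(sim0$reads, anch)
  expect_true(all(nchar(ins0) == full_len))
  # byte-identical FASTQ under the same seed
  cfg <- chimera_sim_config(pair$a$seq, pair$b$seq, n_reads = 100, rho = 0.6,
                            error_rate = 0.01, anchors = anch, seed = 33)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_chimeric_reads(cfg)$reads, f1)
  write_fastq(simulate_chimeric_reads(cfg)$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # empirical chimeric fraction concentrates around rho
  cfg2 <- chimera_sim_config(pair$a$seq, pair$b$seq, linker = "GGTTCCAA",
                             n_reads = 4000, rho = 0.75, anchors = anch,
                             seed = 8)
  sim2 <- simulate_chimeric_reads(cfg2)
  expect_lt(abs(mean(sim2$truth$class == "chimera") - 0.75), 0.03)
})

test_that("error-floor calibration bounds a clean control pool", {
  pair <- make_homolog_pair(80, 0.9, seed = 31)
  anch <- anchor_pair(A5, A3)
  err <- 0.005
  ctl <- simulate_chimeric_reads(chimera_sim_config(
    pair$a$seq, pair$b$seq, n_reads = 2000, rho = 0, error_rate = err,
    anchors = anch, seed = 13, control = TRUE))
  sites <- discriminating_sites(pair$a$seq, pair$b$seq)
  cprof <- analyze_chimeras(ctl$reads, anch, sites)
  expect_lte(max(cprof$profile$frac_acceptor), 3 * err)
  # floor subtraction zeroes a clean pool's own profile
  self <- analyze_chimeras(ctl$reads, anch, sites, control = cprof)
  expect_true(all(self$profile$frac_floored == 0))
  expect_equal(self$error_floor, max(cprof$profile$frac_acceptor))
})

test_that("kept plus dropped reads equals the input at every stage", {
  pair <- make_homolog_pair(50, 0.9, seed = 41)
  anch <- anchor_pair(A5, A3)
  sim <- simulate_chimeric_reads(chimera_sim_config(
    pair$a$seq, pair$b$seq, n_reads = 500, rho = 0.5, error_rate = 0.02,
    anchors = anch, seed = 3))
  ins <- extract_inserts(sim$reads, anch)
  cnt <- attr(ins, "counts")
  expect_equal(unname(cnt["kept"] + cnt["dropped"]), 500L)
  groups <- group_inserts(ins)
  expect_equal(sum(groups$count), unname(cnt["kept"]))
})

test_that("profile TSV round-trips 1-based positions", {
  sites <- discriminating_sites("AAAA", "TTTT")
  prof <- recombination_profile(group_inserts(c("AAAA", "AATT")), sites)
  path <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  tab <- read.delim(path)
  expect_equal(tab$position_1based, sites$positions + 1L)
  expect_equal(tab$frac_acceptor_raw, prof$profile$frac_acceptor)
})
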