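test_that("usage-table loading normalizes fractions and alphabets", {
  tab <- read_codon_usage(toy_usage_tsv(), organism = "toy")
  ala <- tab[tab$amino_acid == "A", ]
  expect_equal(setNames(ala$family_fraction, ala$codon)[c("GCT", "GCC", "GCA", "GCG")],
               c(GCT = 0.3, GCC = 0.4, GCA = 0.2, GCG = 0.1))
  # RNA codons (U) load to the identical table
  tab_rna <- read_codon_usage(toy_usage_tsv(rna = TRUE), organism = "toy")
  expect_equal(tab_rna$codon, tab$codon)
  expect_equal(tab_rna$family_fraction, tab$family_fraction)
  # bundled table: every synonymous family sums to 1 (recomputed here)
  mouse <- codon_usage_mouse()
  expect_equal(nrow(mouse), 61L)
  sums <- tapply(mouse$family_fraction, mouse$amino_acid, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("malformed usage tables are rejected with informative errors", {
  tab <- codon_usage_mouse()
  path <- tempfile(fileext = ".tsv")
  write.table(tab[tab$codon != "GCT", ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_codon_usage(path), "GCT")
  dup <- rbind(tab, tab[1, ])
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_codon_usage(path), "duplicate")
  bad <- tab
  bad$family_fraction[1] <- 1.4
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_codon_usage(path))
  expect_error(read_codon_usage(tempfile()), "cannot read")
})

test_that("kazusa-style free text parses to the same table", {
  tab <- codon_usage_mouse()
  txt <- paste(sprintf("%s %.1f( %d)", chartr("T", "U", tab$codon),
                       tab$per_thousand, round(tab$per_thousand * 1000)),
               collapse = "  ")
  path <- tempfile(fileext = ".txt")
  writeLines(txt, path)
  got <- read_codon_usage(path, dialect = "kazusa_text")
  expect_equal(got$codon, tab$codon)
  expect_equal(got$per_thousand, tab$per_thousand)
})

test_that("serialization round-trips", {
  tab <- codon_usage_mouse()
  path <- tempfile(fileext = ".tsv")
  write_codon_usage(tab, path)
  again <- read_codon_usage(path)
  expect_equal(again$codon, tab$codon)
  expect_equal(again$family_fraction, tab$family_fraction, tolerance = 1e-9)
  # idempotence: a second round-trip is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  write_codon_usage(again, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("abundance filtering orders, thresholds and falls back", {
  tab <- read_codon_usage(toy_usage_tsv(), organism = "toy")
  expect_identical(allowed_codons(tab, 0.20)$A, c("GCC", "GCT", "GCA"))
  expect_identical(allowed_codons(tab, 0)$A, c("GCC", "GCT", "GCA", "GCG"))
  expect_warning(m5 <- allowed_codons(tab, 0.5), "retaining")
  expect_identical(m5$A, "GCC")
  expect_error(allowed_codons(tab, 1.2), "bias")
  # fallback guarantees a non-empty set for every residue at every bias
  for (bias in c(0, 0.25, 0.5, 1)) {
    m <- suppressWarnings(allowed_codons(tab, bias))
    expect_true(all(lengths(m) >= 1L))
    expect_identical(sort(names(m)), sort(unique(tab$amino_acid)))
  }
})

test_that("translation follows the standard code, stop semantics included", {
  expect_identical(translate_cds("ATGGCT")$seq, "MA")
  p <- translate_cds("ATGTAA")
  expect_identical(p$seq, "M")
  expect_true(p$has_stop)
  expect_error(translate_cds("ATGTAAGCT"), "stop")
  expect_error(translate_cds("ATGG"), "divisible")
  expect_error(coding_sequence("ATGN?"), "A/C/G/T")
  # all 61 sense codons against an independently implemented code table
  mouse <- codon_usage_mouse()
  for (cod in mouse$codon)
    expect_identical(translate_cds(paste0("ATG", cod))$seq,
                     toupper(translate_oracle(paste0("ATG", cod))))
})

test_that("back-translation with any allowed map conserves the protein", {
  tab <- codon_usage_mouse()
  set.seed(11)
  for (i in 1:200) {
    bias <- sample(c(0, 0.1, 0.2, 0.3), 1)
    m <- suppressWarnings(allowed_codons(tab, bias))
    p <- make_random_protein(sample(5:60, 1))
    cds <- back_translate(p, m)
    expect_identical(translate_cds(cds)$seq, p$seq)
  }
  # terminal stop is carried through
  stopped <- back_translate(protein_sequence("MA*"), allowed_codons(tab, 0))
  expect_true(endsWith(stopped$seq, "TAA"))
})
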