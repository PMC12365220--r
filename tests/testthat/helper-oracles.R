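# Brute-force oracles, independent of the package's C++ paths: equality-matrix
# dynamic programming for substring statistics, exhaustive enumeration for the
# repeat-interaction objective.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# suffix run-length matrix: R[i, j] = length of the equal run starting at
# (i, j); basis for all three substring oracles
.runlen_matrix <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- outer(av, bv, "==")
  R <- matrix(0L, n, m)
  R[n, ] <- as.integer(M[n, ])
  if (n > 1) for (i in (n - 1):1) {
    nxt <- if (m > 1) c(R[i + 1, 2:m], 0L) else 0L
    R[i, ] <- as.integer(M[i, ]) * (1L + nxt)
  }
  R
}

lcs_oracle <- function(a, b) max(.runlen_matrix(a, b))

mem_oracle <- function(a, b, min_len = 1L) {
  R <- .runlen_matrix(a, b)
  n <- nrow(R); m <- ncol(R)
  # a MEM starts where the diagonal predecessor does not match
  prev <- matrix(FALSE, n, m)
  if (n > 1 && m > 1) prev[2:n, 2:m] <- R[1:(n - 1), 1:(m - 1)] > 0
  start <- R >= min_len & !prev
  idx <- which(start, arr.ind = TRUE)
  data.frame(pos_a = idx[, 1] - 1L, pos_b = idx[, 2] - 1L,
             length = R[start])
}

dotplot_oracle <- function(a, b, k) {
  R <- .runlen_matrix(a, b)
  idx <- which(R >= k, arr.ind = TRUE)
  data.frame(pos_a = idx[, 1] - 1L, pos_b = idx[, 2] - 1L)
}

.sorted_segments <- function(df) {
  df <- df[order(df$pos_a, df$pos_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# exhaustive objective: enumerate maximal exact repeats of C = context || seq
# via the run-length matrix of C against itself, then log-sum-exp by hand
objective_oracle <- function(seq, context = "", params = energy_params()) {
  C <- paste0(context, seq)
  runs <- mem_oracle(C, C, min_len = params$min_match)
  runs <- runs[runs$pos_a < runs$pos_b, , drop = FALSE]
  runs <- runs[runs$pos_b + runs$length > nchar(context), , drop = FALSE]
  if (!nrow(runs)) return(-Inf)
  nn <- params$nn_table
  ee <- vapply(seq_len(nrow(runs)), function(i) {
    s <- substr(C, runs$pos_a[i] + 1L, runs$pos_a[i] + runs$length[i])
    ch <- strsplit(s, "")[[1]]
    dg <- params$init_dg +
      sum(nn[paste0(ch[-length(ch)], ch[-1])])
    -dg / params$rt
  }, numeric(1))
  mx <- max(ee)
  (mx + log(sum(exp(ee - mx)))) / log(10)
}

# independent translation oracle (seqinr's code table, not Biostrings')
translate_oracle <- function(cds) {
  paste(seqinr::translate(strsplit(tolower(cds), "")[[1]]), collapse = "")
}

# toy usage table: mouse values with the alanine family replaced by the given
# per-thousand counts; returns the path of a TSV in the canonical dialect
toy_usage_tsv <- function(ala = c(GCT = 3, GCC = 4, GCA = 2, GCG = 1),
                          rna = FALSE) {
  tab <- codon_usage_mouse()
  tab$per_thousand[match(names(ala), tab$codon)] <- unname(ala)
  tab$family_fraction <- NA_real_
  path <- tempfile(fileext = ".tsv")
  out <- tab[, c("codon", "amino_acid", "family_fraction", "per_thousand")]
  if (rna) out$codon <- chartr("T", "U", out$codon)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
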