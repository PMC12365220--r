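# Synthetic-data generators: random proteins and homologous FP-like CDS
# pairs, so every analysis is testable without external sequence downloads.

#' Random protein sequence
#'
#' Uniform i.i.d. residues over the 20 standard amino acids; deterministic
#' given `seed`.
#'
#' @param length_aa protein length (>= 1).
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @param name label.
#' @return a [protein_sequence()].
#' @export
make_random_protein <- function(length_aa, seed = NULL, name = "random") {
  length_aa <- as.integer(length_aa)
  if (is.na(length_aa) || length_aa < 1L) stop("length_aa must be >= 1",
                                               call. = FALSE)
  .with_seed(seed, {
    protein_sequence(paste(sample(.AA20, length_aa, replace = TRUE),
                           collapse = ""), name = name)
  })
}

.sample_codon <- function(aa, fractions) {
  f <- fractions[[aa]]
  names(f)[sample.int(length(f), 1L, prob = f)]
}

.nt_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

#' Generate a homologous coding-sequence pair
#'
#' Emulates the nucleotide-level relationship between fluorescent-protein
#' coding sequences.  At identity >= 0.90 ("variant pair" regime, like the
#' cyan/yellow derivatives of a common ancestral gene) edits are confined to
#' mutation hotspots in the first ~35% and last ~12% of the gene — mirroring
#' the clustering of FP variant mutations — which leaves a long identical
#' internal stretch, the feature that drives recombination.  Below 0.90
#' ("cross-organism" regime) edits are spread uniformly.  Synonymous edits
#' are exhausted before conservative nonsynonymous ones, so the encoded
#' proteins stay as close as the identity target allows.
#'
#' @param length_aa protein length (default 239, a typical FP).
#' @param identity nucleotide identity target in `[0.5, 1]`; the realized
#'   identity is within 1 percentage point of it.
#' @param seed integer seed; deterministic given it.
#' @param usage codon-usage table used to sample realistic codons.
#' @return list with [coding_sequence()] fields `a` and `b` and the measured
#'   `identity`.
#' @export
make_homolog_pair <- function(length_aa = 239L, identity = 0.95, seed = NULL,
                              usage = codon_usage_mouse()) {
  if (!is.numeric(identity) || identity < 0.5 || identity > 1)
    stop("identity target must be in [0.5, 1]", call. = FALSE)
  length_aa <- as.integer(length_aa)
  if (is.na(length_aa) || length_aa < 10L) stop("length_aa must be >= 10",
                                                call. = FALSE)
  fractions <- attr(allowed_codons(usage, 0), "fractions")
  .with_seed(seed, {
    prot <- strsplit(make_random_protein(length_aa)$seq, "")[[1]]
    codons_a <- vapply(prot, .sample_codon, character(1),
                       fractions = fractions)
    a <- paste(codons_a, collapse = "")
    n_nt <- 3L * length_aa
    target_mm <- round((1 - identity) * n_nt)
    if (identity >= 1) {
      b <- a
    } else if (identity >= 0.90) {
      # hotspot regime: edit only codons in the terminal regions, leaving the
      # central ~53% of the gene untouched (long identical stretch preserved)
      hot <- c(seq_len(floor(0.35 * length_aa)),
               seq.int(ceiling(0.88 * length_aa), length_aa))
      b <- .edit_codons(codons_a, prot, hot, target_mm, fractions)
    } else {
      b <- .edit_codons(codons_a, prot, seq_len(length_aa), target_mm,
                        fractions)
    }
    got <- .nt_identity(a, b)
    if (abs(got - identity) > 0.01)
      stop(sprintf("identity target %.3f unreachable (achieved %.3f)",
                   identity, got), call. = FALSE)
    list(a = coding_sequence(a, name = "homolog_a"),
         b = coding_sequence(b, name = "homolog_b"),
         identity = got)
  })
}

# conservative residue exchanges used when synonymous capacity is exhausted
.CONSERVATIVE <- c(A = "S", C = "S", D = "E", E = "D", F = "Y", G = "A",
                   H = "Q", I = "V", K = "R", L = "I", M = "L", N = "Q",
                   P = "A", Q = "N", R = "K", S = "T", T = "S", V = "I",
                   W = "F", Y = "F")

.codon_mm <- function(c1, c2) {
  sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
}

# Introduce ~target_mm nucleotide mismatches by re-coding codons at the given
# slots: synonymous substitutions first, conservative residue swaps after.
.edit_codons <- function(codons, prot, slots, target_mm, fractions) {
  codons_b <- codons
  mm <- 0L
  all_codons_of <- lapply(fractions, names)
  order1 <- sample(slots)
  for (i in order1) {
    if (mm >= target_mm) break
    syn <- setdiff(all_codons_of[[prot[i]]], codons_b[i])
    if (!length(syn)) next
    d <- vapply(syn, .codon_mm, integer(1), c2 = codons_b[i])
    best <- syn[d == max(d)]
    pick <- best[sample.int(length(best), 1L)]
    codons_b[i] <- pick
    mm <- mm + max(d)
  }
  if (mm < target_mm) {
    order2 <- sample(slots)
    for (i in order2) {
      if (mm >= target_mm) break
      alt_aa <- .CONSERVATIVE[[prot[i]]]
      cur_mm <- .codon_mm(codons_b[i], codons[i])
      cands <- all_codons_of[[alt_aa]]
      d <- vapply(cands, .codon_mm, integer(1), c2 = codons[i])
      gain <- d - cur_mm
      if (max(gain) <= 0) next
      best <- cands[gain == max(gain)]
      codons_b[i] <- best[sample.int(length(best), 1L)]
      mm <- mm + max(gain)
    }
  }
  paste(codons_b, collapse = "")
}
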