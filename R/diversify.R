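# The abundance-biased codon diversification (ABCD) search: choose synonymous
# codons minimizing the repeat-interaction objective f against a reference
# context, restricted to abundance-filtered codons, excluding forbidden
# motifs; with sequential chaining for multi-protein constructs.

#' Construct a forbidden-motif set
#'
#' @param motifs named character vector of DNA motifs (restriction sites,
#'   inverted-terminal-repeat fragments, ...); all non-empty, ACGT-only.
#' @param scan_both_strands also forbid/report occurrences on the reverse
#'   complement strand (default `TRUE`).
#' @return an object of class `motif_set`.
#' @export
motif_set <- function(motifs, scan_both_strands = TRUE) {
  if (!length(motifs)) stop("motif set is empty", call. = FALSE)
  nm <- names(motifs)
  if (is.null(nm)) nm <- rep("", length(motifs))
  nm[!nzchar(nm)] <- paste0("motif", seq_along(motifs))[!nzchar(nm)]
  names(motifs) <- nm
  motifs <- vapply(motifs, .dna_norm, character(1), what = "motif")
  if (any(nchar(motifs) == 0L)) stop("empty motif", call. = FALSE)
  structure(list(motifs = motifs, scan_both_strands = isTRUE(scan_both_strands)),
            class = "motif_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Common restriction-enzyme recognition sites
#'
#' A small set of recognition sites for enzymes routinely used in viral
#' vector cloning, convenient as a default forbidden-motif list.
#'
#' @return named character vector of recognition sequences.
#' @export
restriction_sites <- function() {
  c(EcoRI = "GAATTC", BamHI = "GGATCC", HindIII = "AAGCTT", NheI = "GCTAGC",
    KpnI = "GGTACC", NcoI = "CCATGG", XbaI = "TCTAGA", SalI = "GTCGAC",
    NotI = "GCGGCCGC", AscI = "GGCGCGCC", BsrGI = "TGTACA", SpeI = "ACTAGT")
}

#' Read a motif list from FASTA or one-motif-per-line text
#'
#' @param path input file.  Files starting with `>` are parsed as FASTA;
#'   otherwise each non-empty line is `name<TAB>motif` or a bare motif.
#' @param scan_both_strands passed to [motif_set()].
#' @return a `motif_set`.
#' @export
read_motifs <- function(path, scan_both_strands = TRUE) {
  if (!file.exists(path)) stop("cannot read motif file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    motifs <- read_fasta(path)
  } else {
    ln <- trimws(readLines(path, warn = FALSE))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    parts <- strsplit(ln, "\t")
    motifs <- vapply(parts, function(p) p[length(p)], character(1))
    names(motifs) <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1L) parts[[i]][1] else paste0("motif", i),
      character(1))
  }
  motif_set(motifs, scan_both_strands)
}

#' Scan a sequence for forbidden motifs
#'
#' Reports every occurrence on the forward strand and, when the motif set
#' scans both strands, occurrences whose reverse complement matches (i.e. the
#' motif read on the minus strand).  Overlapping occurrences are reported.
#'
#' @param seq DNA string or [coding_sequence()].
#' @param motifs a [motif_set()].
#' @return data frame with `motif`, `pos` (0-based start on the forward
#'   strand) and `strand` (`"+"`/`"-"`).
#' @export
motif_scan <- function(seq, motifs) {
  stopifnot(inherits(motifs, "motif_set"))
  s <- Biostrings::DNAString(.as_dna(seq, "seq"))
  out <- list()
  for (nm in names(motifs$motifs)) {
    m <- motifs$motifs[[nm]]
    hits <- Biostrings::matchPattern(m, s)
    if (length(hits))
      out[[length(out) + 1L]] <- data.frame(
        motif = nm, pos = BiocGenerics::start(hits) - 1L, strand = "+",
        stringsAsFactors = FALSE)
    if (motifs$scan_both_strands) {
      rc <- .revcomp(m)
      hits <- Biostrings::matchPattern(rc, s)
      if (length(hits))
        out[[length(out) + 1L]] <- data.frame(
          motif = nm, pos = BiocGenerics::start(hits) - 1L, strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$pos, res$motif, res$strand), , drop = FALSE]
}

.motif_strings <- function(motifs) {
  if (is.null(motifs)) return(character(0))
  m <- motifs$motifs
  if (motifs$scan_both_strands) {
    rc <- vapply(m, .revcomp, character(1))
    m <- c(m, rc)
    m <- m[!duplicated(unname(m))]
  }
  m
}

#' Describe a diversification task
#'
#' @param target a [protein_sequence()], [coding_sequence()] or string (amino
#'   acids, or DNA with length divisible by 3).  A terminal stop codon on a
#'   CDS target is copied verbatim to the output and excluded from the search.
#' @param reference_context DNA string the output must be diverse from
#'   (may be empty: internal diversification only).
#' @param allowed an `allowed_codon_map` from [allowed_codons()].
#' @param forbidden optional [motif_set()] that must not occur in the output
#'   nor across the context/output junction.
#' @param seed integer seed; the whole search is deterministic given it.
#' @param budget total annealing iterations (>= 1; see the package vignette
#'   for the default's rationale).
#' @param params an [energy_params()] object.
#' @param restarts annealing phases (the cooling schedule restarts from the
#'   incumbent best between phases).
#' @return an object of class `diversification_task`.
#' @export
diversification_task <- function(target, reference_context = "", allowed,
                                 forbidden = NULL, seed = 1L,
                                 budget = 200000L, params = energy_params(),
                                 restarts = 3L) {
  stopifnot(inherits(allowed, "allowed_codon_map"))
  if (!is.null(forbidden)) stopifnot(inherits(forbidden, "motif_set"))
  if (is.character(target) && !inherits(target, "coding_sequence") &&
      !inherits(target, "protein_sequence")) {
    target <- if (grepl("^[ACGTUacgtu]+$", target) && nchar(target) %% 3L == 0L)
      coding_sequence(target) else protein_sequence(target)
  }
  budget <- as.integer(budget)
  if (is.na(budget) || budget < 1L) stop("budget must be >= 1", call. = FALSE)
  ctx <- if (is.null(reference_context) || !nzchar(reference_context)) ""
         else .as_dna(reference_context, "reference_context")
  structure(list(target = target, reference_context = ctx, allowed = allowed,
                 forbidden = forbidden, seed = as.integer(seed),
                 budget = budget, params = params,
                 restarts = as.integer(restarts)),
            class = "diversification_task")
}

.codon_code <- function(codon) {
  b <- match(strsplit(codon, "")[[1]], c("A", "C", "G", "T")) - 1L
  b[1] * 16L + b[2] * 4L + b[3]
}

.code_codon <- function(code) {
  b <- c("A", "C", "G", "T")
  paste0(b[code %/% 16L + 1L], b[(code %/% 4L) %% 4L + 1L], b[code %% 4L + 1L])
}

#' Run an abundance-biased codon diversification
#'
#' Greedy left-to-right codon construction (scored by the incremental
#' objective against the reference context plus the already-built prefix,
#' with bounded backtracking over forbidden-motif conflicts) followed by
#' simulated-annealing refinement over random synonymous swaps.  The search
#' is deterministic given the task seed.
#'
#' @param task a [diversification_task()].
#' @return an object of class `diversification_result` with fields `output`
#'   (a [coding_sequence()]), `fscore_vs_reference`, `fscore_internal`,
#'   `max_identical_bp` (longest identical stretch vs the reference context),
#'   `codon_counts`, `seed`, `iterations_used`, `bias`.
#' @examples
#' map <- allowed_codons(codon_usage_mouse(), bias = 0.2)
#' task <- diversification_task("MA", allowed = map, budget = 10)
#' diversify(task)$output$seq
#' @export
diversify <- function(task) {
  stopifnot(inherits(task, "diversification_task"))
  prot <- .as_protein(task$target)
  fixed_suffix <- ""
  if (inherits(task$target, "coding_sequence") && prot$has_stop) {
    n <- nchar(task$target$seq)
    fixed_suffix <- substr(task$target$seq, n - 2L, n)
  } else if (prot$has_stop) {
    fixed_suffix <- "TAA"
  }
  residues <- strsplit(prot$seq, "")[[1]]
  fr <- attr(task$allowed, "fractions")
  allowed_codes <- lapply(residues, function(a) {
    cods <- task$allowed[[a]]
    if (is.null(cods)) stop("no allowed codons for residue ", a, call. = FALSE)
    vapply(cods, .codon_code, integer(1))
  })
  frac_list <- lapply(residues, function(a) unname(fr[[a]]))
  mot <- .motif_strings(task$forbidden)

  r <- cpp_diversify(task$reference_context, allowed_codes, frac_list,
                     unname(mot), names(mot) %||% character(0),
                     task$params$stacks, task$params$rt,
                     task$params$init_dg, task$params$min_match, fixed_suffix,
                     task$budget, task$seed, task$restarts, 1.0, 0.01)

  out <- coding_sequence(r$seq, name = if (nzchar(prot$name))
    paste0("cd", prot$name) else "diversified")
  # verify the contracts the search must satisfy
  stopifnot(identical(translate_cds(out)$seq, prot$seq))
  if (!is.null(task$forbidden)) {
    junction <- nchar(task$reference_context) > 0L
    scan_seq <- if (junction) {
      maxlen <- max(nchar(task$forbidden$motifs))
      paste0(substr(task$reference_context,
                    max(1L, nchar(task$reference_context) - maxlen + 2L),
                    nchar(task$reference_context)), out$seq)
    } else out$seq
    hits <- motif_scan(scan_seq, task$forbidden)
    if (nrow(hits))
      stop("internal error: forbidden motif in output", call. = FALSE)
  }
  fs_ref <- if (nzchar(task$reference_context))
    pair_f(task$reference_context, out, task$params)
  else objective_f(out, params = task$params)
  fs_int <- objective_f(out, params = task$params)
  max_ident <- if (nzchar(task$reference_context))
    longest_common_substring(out$seq, task$reference_context)$length else 0L
  codons <- substring(out$seq, seq(1L, nchar(out$seq), 3L),
                      seq(3L, nchar(out$seq), 3L))
  if (nzchar(fixed_suffix)) codons <- codons[-length(codons)]
  structure(list(output = out,
                 fscore_vs_reference = fs_ref,
                 fscore_internal = fs_int,
                 max_identical_bp = max_ident,
                 codon_counts = table(codons),
                 seed = task$seed,
                 iterations_used = r$iterations,
                 bias = attr(task$allowed, "bias")),
            class = "diversification_result")
}

#' @export
print.diversification_result <- function(x, ...) {
  cat(sprintf("diversification_result: %d bp; f vs reference = %s; longest identical stretch vs reference = %d bp\n",
              nchar(x$output$seq), format(x$fscore_vs_reference),
              x$max_identical_bp))
  invisible(x)
}

#' Sequentially diversify several targets against a growing shared reference
#'
#' Target `i` is diversified against `shared_reference` concatenated with the
#' outputs of targets `1 .. i-1`, so that every output is diverse both from
#' the shared reference and from every other output.
#'
#' @param tasks list (length >= 2) of [diversification_task()] templates; the
#'   `reference_context` of each is replaced by the growing chain reference.
#' @param shared_reference DNA string all outputs must be diverse from.
#' @return list with `results` (one `diversification_result` per target) and
#'   `max_identical_bp` (symmetric matrix of longest identical stretches over
#'   `{shared_reference, outputs}`).
#' @export
diversify_chain <- function(tasks, shared_reference = "") {
  if (length(tasks) < 2L) stop("chain needs at least two targets", call. = FALSE)
  ref <- if (nzchar(shared_reference)) .as_dna(shared_reference, "shared_reference") else ""
  results <- vector("list", length(tasks))
  for (i in seq_along(tasks)) {
    t <- tasks[[i]]
    stopifnot(inherits(t, "diversification_task"))
    t$reference_context <- ref
    results[[i]] <- diversify(t)
    ref <- paste0(ref, results[[i]]$output$seq)
  }
  seqs <- c(if (nzchar(shared_reference)) list(reference = shared_reference) else NULL,
            setNames(lapply(results, function(r) r$output$seq),
                     paste0("output", seq_along(results))))
  k <- length(seqs)
  mat <- matrix(0L, k, k, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    mat[i, j] <- longest_common_substring(seqs[[i]], seqs[[j]])$length
  list(results = results, max_identical_bp = mat)
}
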