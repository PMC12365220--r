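# Long-read recombination analysis: anchor-based insert extraction, exact
# grouping, donor/acceptor position calling, cumulative recombination profile
# with linear fit, and a matching chimeric-read simulator.

#' Anchor pair for insert extraction
#'
#' @param anchor5,anchor3 DNA anchors (>= 10 bp) flanking the insert: the
#'   expected stretch downstream of the forward primer binding site and the
#'   stretch upstream of the reverse one.
#' @param max_mismatch maximum Hamming mismatches tolerated per anchor.
#' @return an object of class `anchor_pair`.
#' @export
anchor_pair <- function(anchor5, anchor3, max_mismatch = 0L) {
  anchor5 <- .dna_norm(anchor5, "anchor5")
  anchor3 <- .dna_norm(anchor3, "anchor3")
  if (nchar(anchor5) < 10L || nchar(anchor3) < 10L)
    stop("anchors must be at least 10 bp", call. = FALSE)
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L)
    stop("max_mismatch must be >= 0", call. = FALSE)
  structure(list(anchor5 = anchor5, anchor3 = anchor3,
                 max_mismatch = max_mismatch), class = "anchor_pair")
}

.anchor_starts <- function(reads, anchor, max_mismatch) {
  m <- Biostrings::vmatchPattern(anchor, reads, max.mismatch = max_mismatch,
                                 fixed = TRUE)
  Biostrings::startIndex(m)
}

#' Extract inserts between two anchors
#'
#' A read is kept iff each anchor matches exactly once (Hamming distance
#' `<= max_mismatch`) with the 5' anchor upstream of the 3' one; the sequence
#' between the anchors is returned.  Reads failing forward matching are
#' retried as their reverse complement (orientation normalization).
#'
#' @param reads a [Biostrings::DNAStringSet], character vector of reads, or
#'   path to a FASTQ file.
#' @param anchors an [anchor_pair()].
#' @return character vector of inserts, with attribute `counts` (named:
#'   `input`, `kept`, `dropped`) recording conservation of reads.
#' @export
extract_inserts <- function(reads, anchors) {
  stopifnot(inherits(anchors, "anchor_pair"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  if (!methods::is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(reads)
  n_in <- length(reads)
  inserts <- character(0)
  if (n_in > 0L) {
    seqs <- reads
    len5 <- nchar(anchors$anchor5)
    res <- rep(NA_character_, n_in)
    for (pass in 1:2) {
      todo <- which(is.na(res))
      if (!length(todo)) break
      if (pass == 2L) seqs <- Biostrings::reverseComplement(seqs)
      s5 <- .anchor_starts(seqs[todo], anchors$anchor5, anchors$max_mismatch)
      s3 <- .anchor_starts(seqs[todo], anchors$anchor3, anchors$max_mismatch)
      ok <- lengths(s5) == 1L & lengths(s3) == 1L
      if (!any(ok)) next
      a <- unlist(s5[ok], use.names = FALSE)
      b <- unlist(s3[ok], use.names = FALSE)
      good <- a + len5 <= b
      idx <- todo[ok][good]
      if (length(idx))
        res[idx] <- substring(as.character(seqs[idx]), a[good] + len5,
                              b[good] - 1L)
    }
    inserts <- res[!is.na(res)]
  }
  structure(inserts,
            counts = c(input = n_in, kept = length(inserts),
                       dropped = n_in - length(inserts)))
}

#' Group identical inserts
#'
#' Exact-string grouping with counts, ordered by descending count then
#' lexicographically.
#'
#' @param inserts character vector of inserts.
#' @return data frame with columns `insert` and `count` (class `read_groups`).
#' @export
group_inserts <- function(inserts) {
  if (!length(inserts))
    return(structure(data.frame(insert = character(0), count = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("read_groups", "data.frame")))
  tb <- table(inserts)
  df <- data.frame(insert = names(tb), count = as.integer(tb),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$insert), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("read_groups", "data.frame"))
}

#' Discriminating positions between colinear donor and acceptor sequences
#'
#' @param donor,acceptor equal-length DNA strings of the two fluorescent
#'   protein coding sequences.
#' @return object of class `discriminating_sites`: `donor`, `acceptor` and
#'   0-based `positions` at which they differ.
#' @export
discriminating_sites <- function(donor, acceptor) {
  donor <- .as_dna(donor, "donor"); acceptor <- .as_dna(acceptor, "acceptor")
  if (nchar(donor) != nchar(acceptor))
    stop("donor and acceptor must have equal length (positional colinearity)",
         call. = FALSE)
  d <- strsplit(donor, "")[[1]]; a <- strsplit(acceptor, "")[[1]]
  pos <- which(d != a) - 1L
  if (!length(pos)) stop("donor and acceptor are identical: no discriminating positions",
                         call. = FALSE)
  structure(list(donor = donor, acceptor = acceptor, positions = pos),
            class = "discriminating_sites")
}

#' Call a read group at the discriminating positions
#'
#' At each discriminating position the group is lettered `C` (matches the
#' donor) or `Y` (matches the acceptor).  A nucleotide matching neither is
#' interpreted as a sequencing error and discards the whole group; an insert
#' length different from the reference length is discarded with reason
#' `"length"`.
#'
#' @param group one-row data frame (or list) with `insert` and `count`.
#' @param sites a [discriminating_sites()] object.
#' @return list with `status` (`"ok"` or `"discard"`), `reason` (`NA`,
#'   `"length"` or `"error"`), and `calls` (character vector of `C`/`Y` per
#'   discriminating position when `status == "ok"`).
#' @export
call_group <- function(group, sites) {
  stopifnot(inherits(sites, "discriminating_sites"))
  insert <- group$insert
  if (nchar(insert) != nchar(sites$donor))
    return(list(status = "discard", reason = "length", calls = NULL))
  p <- sites$positions + 1L
  nt <- substring(insert, p, p)
  dn <- substring(sites$donor, p, p)
  ac <- substring(sites$acceptor, p, p)
  calls <- ifelse(nt == dn, "C", ifelse(nt == ac, "Y", NA_character_))
  if (anyNA(calls))
    return(list(status = "discard", reason = "error", calls = NULL))
  list(status = "ok", reason = NA_character_, calls = calls)
}

#' Cumulative recombination profile from grouped reads
#'
#' For each discriminating position `p`, the count-weighted fraction of valid
#' groups calling the acceptor letter at `p` estimates the fraction of
#' molecules that had recombined before `p`.  A least-squares line is fitted
#' to fraction versus position (bp); under breakpoints of equal probability
#' at every position the profile is linear.  `chimeric_fraction` is the
#' fraction of anchored inserts whose length equals the single-FP reference
#' length (recombinants) among all anchored inserts.
#'
#' @param groups a `read_groups` data frame from [group_inserts()].
#' @param sites a [discriminating_sites()] object.
#' @param control optional `recombination_profile` of a non-recombined
#'   control pool; its maximum per-position fraction defines `error_floor`,
#'   and floor-subtracted fractions (clamped at 0) are reported alongside the
#'   raw ones.
#' @return object of class `recombination_profile`: `profile` (data frame
#'   `position`, `n_valid`, `frac_acceptor`, `frac_floored`), `fit` (`slope`,
#'   `intercept`, `r2`), `chimeric_fraction`, `error_floor`, `counts`.
#' @export
recombination_profile <- function(groups, sites, control = NULL) {
  stopifnot(inherits(sites, "discriminating_sites"))
  if (!nrow(groups)) stop("no read groups", call. = FALSE)
  n_ref <- nchar(sites$donor)
  total_reads <- sum(groups$count)
  is_fp_len <- nchar(groups$insert) == n_ref
  chim_frac <- sum(groups$count[is_fp_len]) / total_reads
  cand <- groups[is_fp_len, , drop = FALSE]
  npos <- length(sites$positions)
  acc_w <- numeric(npos)
  n_valid <- 0L
  n_err <- 0L
  for (i in seq_len(nrow(cand))) {
    cg <- call_group(cand[i, ], sites)
    if (cg$status != "ok") {
      n_err <- n_err + 1L
      next
    }
    acc_w <- acc_w + cand$count[i] * (cg$calls == "Y")
    n_valid <- n_valid + cand$count[i]
  }
  if (n_valid == 0L) stop("no valid (error-free, full-length) read group",
                          call. = FALSE)
  frac <- acc_w / n_valid
  floor_ <- 0
  if (!is.null(control)) {
    stopifnot(inherits(control, "recombination_profile"))
    floor_ <- max(control$profile$frac_acceptor)
  }
  floored <- pmax(0, frac - floor_)
  pos <- sites$positions
  fit <- lm(frac ~ pos)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((frac - mean(frac))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(
    profile = data.frame(position = pos, n_valid = n_valid,
                         frac_acceptor = frac, frac_floored = floored),
    fit = list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               r2 = r2),
    chimeric_fraction = chim_frac,
    error_floor = floor_,
    counts = c(groups = nrow(groups), called = nrow(cand) - n_err,
               discarded_error = n_err,
               length_mismatch = sum(!is_fp_len))),
    class = "recombination_profile")
}

#' @export
print.recombination_profile <- function(x, ...) {
  cat(sprintf("recombination_profile: %d discriminating positions, %d weighted valid reads\n",
              nrow(x$profile), x$profile$n_valid[1]))
  cat(sprintf("  chimeric fraction %.3f; linear fit slope %.3g /bp, R^2 %.4f\n",
              x$chimeric_fraction, x$fit$slope, x$fit$r2))
  invisible(x)
}

#' Write a recombination profile as TSV
#'
#' Columns `position_1based`, `n_valid`, `frac_acceptor_raw`,
#' `frac_acceptor_floored`.
#'
#' @param profile a `recombination_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  p <- profile$profile
  out <- data.frame(position_1based = p$position + 1L, n_valid = p$n_valid,
                    frac_acceptor_raw = p$frac_acceptor,
                    frac_acceptor_floored = p$frac_floored)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Configuration for the chimeric-read simulator
#'
#' @param donor,acceptor equal-length DNA strings (the two FP coding
#'   sequences of a sensor).
#' @param linker DNA between them in the full (non-recombined) construct.
#' @param n_reads number of reads to simulate.
#' @param rho fraction of molecules that recombined (`[0, 1]`).
#' @param breakpoint_dist `"uniform"`, or a numeric weight vector over the
#'   discriminating span for custom breakpoint densities.
#' @param error_rate i.i.d. per-base substitution probability (`[0, 0.5)`).
#' @param anchors an [anchor_pair()] wrapped around every insert.
#' @param seed integer seed; simulation is deterministic given it.
#' @param control simulate a non-recombined single-FP (pure donor) pool, as
#'   used to calibrate the sequencing-error floor.
#' @return an object of class `chimera_sim_config`.
#' @export
chimera_sim_config <- function(donor, acceptor, linker = "", n_reads = 1000L,
                               rho = 0.5, breakpoint_dist = "uniform",
                               error_rate = 0, anchors, seed = 1L,
                               control = FALSE) {
  donor <- .as_dna(donor, "donor"); acceptor <- .as_dna(acceptor, "acceptor")
  if (nchar(donor) != nchar(acceptor))
    stop("donor and acceptor must have equal length", call. = FALSE)
  if (!is.numeric(rho) || rho < 0 || rho > 1) stop("rho must be in [0, 1]",
                                                   call. = FALSE)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  stopifnot(inherits(anchors, "anchor_pair"))
  if (nzchar(linker)) linker <- .dna_norm(linker, "linker")
  structure(list(donor = donor, acceptor = acceptor, linker = linker,
                 n_reads = as.integer(n_reads), rho = rho,
                 breakpoint_dist = breakpoint_dist, error_rate = error_rate,
                 anchors = anchors, seed = as.integer(seed),
                 control = isTRUE(control)),
            class = "chimera_sim_config")
}

.mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < error_rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate an anchored chimeric read pool
#'
#' Each read is, with probability `rho`, a chimera `donor[0:b] || acceptor[b:n]`
#' with breakpoint `b` drawn over the discriminating span, and otherwise the
#' full construct `donor || linker || acceptor` (or the pure donor when
#' `control = TRUE`).  Inserts are wrapped in the anchors plus short random
#' flanks, substitution errors are applied i.i.d., and qualities are constant.
#'
#' @param config a [chimera_sim_config()].
#' @return list with `reads` (a [Biostrings::QualityScaledDNAStringSet]) and
#'   `truth` (data frame `read`, `class`, `breakpoint`; breakpoint `NA` for
#'   non-chimeric reads).
#' @export
simulate_chimeric_reads <- function(config) {
  stopifnot(inherits(config, "chimera_sim_config"))
  .with_seed(config$seed, {
    n <- nchar(config$donor)
    sites <- discriminating_sites(config$donor, config$acceptor)
    span <- range(sites$positions)          # 0-based
    lo <- span[1] + 1L; hi <- span[2]       # breakpoints b: donor < b, acceptor >= b
    bp_support <- lo:hi
    weights <- if (identical(config$breakpoint_dist, "uniform"))
      rep(1, length(bp_support))
    else {
      w <- config$breakpoint_dist
      if (!is.numeric(w) || length(w) != length(bp_support) || any(w < 0) ||
          sum(w) <= 0)
        stop("custom breakpoint weights must be a non-negative numeric vector over the discriminating span (length ",
             length(bp_support), ")", call. = FALSE)
      w
    }
    full <- if (config$control) config$donor
            else paste0(config$donor, config$linker, config$acceptor)
    is_chim <- runif(config$n_reads) < config$rho
    if (config$control) is_chim[] <- FALSE
    bps <- rep(NA_integer_, config$n_reads)
    nc <- sum(is_chim)
    if (nc > 0)
      bps[is_chim] <- sample(bp_support, nc, replace = TRUE, prob = weights)
    bp0 <- ifelse(is.na(bps), 1L, bps)
    inserts <- ifelse(is_chim,
                      paste0(substring(config$donor, 1L, bp0),
                             substring(config$acceptor, bp0 + 1L, n)),
                      full)
    bases <- c("A", "C", "G", "T")
    flank5 <- vapply(seq_len(config$n_reads), function(i)
      paste(sample(bases, 8L, replace = TRUE), collapse = ""), character(1))
    flank3 <- vapply(seq_len(config$n_reads), function(i)
      paste(sample(bases, 8L, replace = TRUE), collapse = ""), character(1))
    reads <- paste0(flank5, config$anchors$anchor5, inserts,
                    config$anchors$anchor3, flank3)
    reads <- .mutate_reads(reads, config$error_rate)
    ids <- sprintf("read%06d", seq_len(config$n_reads))
    dss <- Biostrings::DNAStringSet(setNames(reads, ids))
    qual <- Biostrings::PhredQuality(vapply(nchar(reads), function(L)
      paste(rep("I", L), collapse = ""), character(1)))
    qs <- Biostrings::QualityScaledDNAStringSet(dss, qual)
    truth <- data.frame(read = ids,
                        class = ifelse(is_chim, "chimera",
                                       if (config$control) "donor" else "full"),
                        breakpoint = bps, stringsAsFactors = FALSE)
    list(reads = qs, truth = truth)
  })
}

#' Write simulated reads as FASTQ (Sanger qualities)
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, filepath = path)
  invisible(path)
}

#' Full analysis of an anchored read pool
#'
#' Convenience pipeline: extract inserts, group them, call groups and build
#' the recombination profile.
#'
#' @param reads reads (see [extract_inserts()]).
#' @param anchors an [anchor_pair()].
#' @param sites a [discriminating_sites()] object.
#' @param control optional control pool profile (see
#'   [recombination_profile()]).
#' @return a `recombination_profile`.
#' @export
analyze_chimeras <- function(reads, anchors, sites, control = NULL) {
  inserts <- extract_inserts(reads, anchors)
  groups <- group_inserts(inserts)
  recombination_profile(groups, sites, control = control)
}
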