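# Exact-repeat diagnostics between sequence pairs: longest identical stretch,
# maximal-exact-match length distribution, dot plots.

#' Longest common substring of two DNA sequences
#'
#' Returns one witnessing occurrence of a maximal-length shared substring.
#' Positions are 0-based.  If the sequences share no character the sentinel
#' `length = 0` segment is returned (positions `NA`).
#'
#' @param a,b DNA strings or [coding_sequence()] objects; both non-empty.
#' @return one-row data frame with `pos_a`, `pos_b`, `length`.
#' @examples
#' longest_common_substring("ACGT", "ACGT")
#' @export
longest_common_substring <- function(a, b) {
  a <- .as_dna(a, "a"); b <- .as_dna(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("both sequences must be non-empty", call. = FALSE)
  r <- cpp_lcs(a, b)
  if (r$length == 0L)
    return(data.frame(pos_a = NA_integer_, pos_b = NA_integer_, length = 0L))
  data.frame(pos_a = r$pos_a, pos_b = r$pos_b, length = r$length)
}

#' Maximal exact matches between two DNA sequences
#'
#' A maximal exact match (MEM) is a shared substring that cannot be extended
#' on either side.  The MEM length histogram summarizes the repeat structure
#' of a sequence pair; its maximum equals the longest common substring.
#'
#' @param a,b DNA strings; non-empty.
#' @param min_len report only MEMs of at least this length (bp).
#' @return data frame with 0-based `pos_a`, `pos_b` and `length`.
#' @export
maximal_exact_matches <- function(a, b, min_len = 1L) {
  a <- .as_dna(a, "a"); b <- .as_dna(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("both sequences must be non-empty", call. = FALSE)
  if (!is.numeric(min_len) || min_len < 1) stop("min_len must be >= 1",
                                                call. = FALSE)
  cpp_mems(a, b, as.integer(min_len))
}

#' Dot-plot word matches between two DNA sequences
#'
#' Every position pair `(i, j)` (0-based) at which the length-`k` words of the
#' two sequences agree.  In `"both"` strand mode, matches against the reverse
#' complement of `b` are also reported with `strand = "-"`; their `pos_b` is
#' the 0-based start of the matched window on the forward coordinates of `b`.
#'
#' @param a,b DNA strings.
#' @param k word size, `1 <= k <= min(nchar(a), nchar(b))`.
#' @param strand_mode `"forward_only"` (default; recombination acts on
#'   same-sense repeats) or `"both"`.
#' @return data frame with `pos_a`, `pos_b`, `length` (`== k`), `strand`.
#' @export
dotplot_matches <- function(a, b, k, strand_mode = c("forward_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  a <- .as_dna(a, "a"); b <- .as_dna(b, "b")
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > min(nchar(a), nchar(b)))
    stop("k must satisfy 1 <= k <= min(|a|, |b|)", call. = FALSE)
  fw <- cpp_dotplot(a, b, k)
  out <- data.frame(pos_a = fw$pos_a, pos_b = fw$pos_b,
                    length = rep(k, nrow(fw)),
                    strand = rep("+", nrow(fw)), stringsAsFactors = FALSE)
  if (strand_mode == "both") {
    rv <- cpp_dotplot(a, .revcomp(b), k)
    if (nrow(rv)) {
      out <- rbind(out, data.frame(pos_a = rv$pos_a,
                                   pos_b = nchar(b) - rv$pos_b - k,
                                   length = k, strand = "-",
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$pos_a, out$pos_b, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Homology report for a sequence pair
#'
#' Bundles the longest identical stretch, the MEM length histogram and the
#' dot-plot record list for a pair of sequences.
#'
#' @param a,b DNA strings.
#' @param k dot-plot word size.
#' @param min_len minimum MEM length entering the histogram.
#' @param strand_mode passed to [dotplot_matches()].
#' @return an object of class `homology_report` with elements `lcs`,
#'   `mem_histogram` (data frame `length_bp`, `count`), `dotplot`,
#'   `strand_mode`.
#' @export
homology_report <- function(a, b, k = 8L, min_len = 1L,
                            strand_mode = c("forward_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  a <- .as_dna(a, "a"); b <- .as_dna(b, "b")
  mem <- maximal_exact_matches(a, b, min_len = min_len)
  hist <- as.data.frame(table(mem$length), stringsAsFactors = FALSE)
  names(hist) <- c("length_bp", "count")
  hist$length_bp <- as.integer(hist$length_bp)
  structure(list(lcs = longest_common_substring(a, b),
                 mem_histogram = hist,
                 dotplot = dotplot_matches(a, b, k, strand_mode),
                 k = as.integer(k), strand_mode = strand_mode),
            class = "homology_report")
}

#' @export
print.homology_report <- function(x, ...) {
  cat(sprintf("homology_report: longest identical stretch %d bp; %d MEM(s); %d dot-plot match(es) at k = %d\n",
              x$lcs$length, sum(x$mem_histogram$count), nrow(x$dotplot), x$k))
  invisible(x)
}

#' Write a dot plot as 3-column TSV
#'
#' Columns `pos_a_1based`, `pos_b_1based`, `strand`.
#'
#' @param dotplot data frame from [dotplot_matches()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dotplot_tsv <- function(dotplot, path) {
  out <- data.frame(pos_a_1based = dotplot$pos_a + 1L,
                    pos_b_1based = dotplot$pos_b + 1L,
                    strand = dotplot$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a MEM length histogram as 2-column TSV
#'
#' Columns `length_bp`, `count`.
#'
#' @param report a `homology_report` (or a histogram data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mem_histogram_tsv <- function(report, path) {
  hist <- if (inherits(report, "homology_report")) report$mem_histogram else report
  write.table(hist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
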