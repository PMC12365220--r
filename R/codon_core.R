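# Sequence primitives, genetic code, codon-usage parsing and abundance-bias
# filtering.

.SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
})

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.AA20 <- sort(unique(unname(Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])))

#' Construct a validated coding sequence
#'
#' A coding sequence is an uppercase DNA string over A/C/G/T whose length is a
#' multiple of three.  `U` is normalized to `T`.
#'
#' @param seq DNA string.
#' @param name optional label.
#' @return an object of class `coding_sequence` with fields `seq` and `name`.
#' @examples
#' coding_sequence("ATGGCT", name = "demo")
#' @export
coding_sequence <- function(seq, name = "") {
  s <- .dna_norm(seq, "coding sequence")
  if (nchar(s) == 0L) stop("coding sequence is empty", call. = FALSE)
  if (nchar(s) %% 3L != 0L)
    stop("coding sequence length ", nchar(s), " is not divisible by 3",
         call. = FALSE)
  structure(list(seq = s, name = as.character(name)), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("coding_sequence", if (nzchar(x$name)) paste0("'", x$name, "'") else "",
      sprintf("(%d bp, %d codons)\n", nchar(x$seq), nchar(x$seq) %/% 3L))
  invisible(x)
}

#' Construct a validated protein sequence
#'
#' One-letter amino-acid string over the 20 standard residues; a single
#' terminal `*` is accepted and recorded in `has_stop`.
#'
#' @param seq amino-acid string, optionally `*`-terminated.
#' @param name optional label.
#' @return an object of class `protein_sequence` with fields `seq`, `has_stop`
#'   and `name`.
#' @export
protein_sequence <- function(seq, name = "") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop("protein must be a single character string", call. = FALSE)
  s <- toupper(seq)
  has_stop <- grepl("\\*$", s)
  if (has_stop) s <- sub("\\*$", "", s)
  if (nchar(s) == 0L) stop("empty protein", call. = FALSE)
  bad <- setdiff(strsplit(s, "")[[1]], .AA20)
  if (length(bad))
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  structure(list(seq = s, has_stop = has_stop, name = as.character(name)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("protein_sequence %s(%d aa%s)\n",
              if (nzchar(x$name)) paste0("'", x$name, "' ") else "",
              nchar(x$seq), if (x$has_stop) ", terminal stop" else ""))
  invisible(x)
}

#' Translate a coding sequence
#'
#' Standard genetic code.  An internal stop codon is an error; a terminal stop
#' sets `has_stop` on the result.
#'
#' @param cds a [coding_sequence()] or DNA string with length divisible by 3.
#' @return a [protein_sequence()].
#' @examples
#' translate_cds("ATGGCT")$seq  # "MA"
#' @export
translate_cds <- function(cds) {
  if (inherits(cds, "coding_sequence")) {
    s <- cds$seq
    nm <- cds$name
  } else {
    nm <- ""
    s <- .dna_norm(cds, "coding sequence")
    if (nchar(s) %% 3L != 0L)
      stop("length not divisible by 3", call. = FALSE)
  }
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- which(aa == "*")
  has_stop <- FALSE
  if (length(stops)) {
    if (any(stops < length(aa)))
      stop("internal stop codon at codon ", stops[stops < length(aa)][1],
           call. = FALSE)
    has_stop <- TRUE
    aa <- aa[-length(aa)]
    if (!length(aa)) stop("coding sequence is a bare stop codon", call. = FALSE)
  }
  p <- protein_sequence(paste(aa, collapse = ""), name = nm)
  p$has_stop <- has_stop
  p
}

.validate_usage <- function(df, organism) {
  df$codon <- toupper(chartr("Uu", "Tt", df$codon))
  if (anyDuplicated(df$codon))
    stop("duplicate codon(s): ",
         paste(unique(df$codon[duplicated(df$codon)]), collapse = ", "),
         call. = FALSE)
  df <- df[!(df$codon %in% .STOP_CODONS), , drop = FALSE]
  missing <- setdiff(.SENSE_CODONS, df$codon)
  if (length(missing))
    stop("missing sense codon(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(df$codon, .SENSE_CODONS)
  if (length(extra))
    stop("unknown codon(s): ", paste(extra, collapse = ", "), call. = FALSE)
  df$amino_acid <- unname(Biostrings::GENETIC_CODE[df$codon])
  if (any(!is.finite(df$per_thousand)) || any(df$per_thousand < 0))
    stop("per_thousand values must be non-negative", call. = FALSE)
  # derive family fractions from per-thousand counts when absent
  fam_tot <- tapply(df$per_thousand, df$amino_acid, sum)
  if (all(is.na(df$family_fraction))) {
    if (any(fam_tot <= 0))
      stop("cannot derive fractions: zero-usage amino-acid family", call. = FALSE)
    df$family_fraction <- as.numeric(df$per_thousand / fam_tot[df$amino_acid])
  }
  if (any(df$family_fraction < 0 | df$family_fraction > 1, na.rm = TRUE) ||
      any(is.na(df$family_fraction)))
    stop("family_fraction outside [0, 1]", call. = FALSE)
  sums <- tapply(df$family_fraction, df$amino_acid, sum)
  off <- names(sums)[abs(sums - 1) > 1e-6]
  if (length(off))
    stop("family fractions do not sum to 1 for: ", paste(off, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$amino_acid, -df$family_fraction, df$codon), ]
  rownames(df) <- NULL
  structure(df[, c("codon", "amino_acid", "family_fraction", "per_thousand")],
            organism = organism, class = c("codon_usage", "data.frame"))
}

#' Read a codon-usage table
#'
#' Two dialects are supported.  `"tsv"` is the package's canonical 4-column
#' tab-separated format (`codon`, `amino_acid`, `family_fraction`,
#' `per_thousand`; the fraction column may be empty, in which case fractions
#' are derived from the per-thousand counts).  `"kazusa_text"` parses the
#' free-text codon-usage block format (`"UUU 17.2( 714298)"` fields).
#' RNA codons (`U`) are normalized to DNA (`T`).
#'
#' @param path file to read (or, for `kazusa_text`, a file whose whole content
#'   is the usage block).
#' @param dialect `"tsv"` or `"kazusa_text"`.
#' @param organism label stored on the table.
#' @return a `codon_usage` data frame with all 61 sense codons; within each
#'   synonymous family the fractions sum to 1.
#' @export
read_codon_usage <- function(path, dialect = c("tsv", "kazusa_text"),
                             organism = "unknown") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("cannot read codon usage table: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("codon", "per_thousand")
    if (!all(need %in% names(df)))
      stop("tsv usage table needs columns codon and per_thousand", call. = FALSE)
    if (!"family_fraction" %in% names(df)) df$family_fraction <- NA_real_
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = " ")
    m <- gregexpr("([ACGTUacgtu]{3})\\s+([0-9.]+)\\s*\\(\\s*([0-9]+)\\s*\\)", txt)
    hits <- regmatches(txt, m)[[1]]
    if (!length(hits)) stop("no codon entries found in kazusa-style text",
                            call. = FALSE)
    codon <- toupper(sub("^([ACGTUacgtu]{3}).*", "\\1", hits))
    per_thousand <- as.numeric(sub("^[ACGTUacgtu]{3}\\s+([0-9.]+).*", "\\1", hits))
    df <- data.frame(codon = codon, per_thousand = per_thousand,
                     family_fraction = NA_real_, stringsAsFactors = FALSE)
  }
  .validate_usage(df, organism)
}

#' Write a codon-usage table in the canonical TSV dialect
#'
#' @param table a `codon_usage` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codon_usage <- function(table, path) {
  stopifnot(inherits(table, "codon_usage"))
  out <- table
  out$family_fraction <- sprintf("%.10f", out$family_fraction)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled mouse-style codon-usage table
#'
#' A representative murine codon-usage table assembled from commonly cited
#' usage statistics (synthetic stand-in for an organism-database download;
#' see the shipped file `extdata/codon_usage_mouse_synthetic.tsv`).
#'
#' @return a `codon_usage` table.
#' @export
codon_usage_mouse <- function() {
  read_codon_usage(system.file("extdata", "codon_usage_mouse_synthetic.tsv",
                               package = "abcd", mustWork = TRUE),
                   dialect = "tsv", organism = "mouse (representative)")
}

#' Abundance-filtered synonymous codon sets
#'
#' For each amino acid, keeps the codons whose within-family usage fraction is
#' at least `bias`, ordered by descending fraction.  When no codon of a family
#' qualifies, the family's single most abundant codon is retained so that
#' every residue stays encodable (a warning names the affected residues).
#'
#' @param table a `codon_usage` table.
#' @param bias abundance floor in `[0, 1]`.
#' @return an `allowed_codon_map`: named list (one element per amino acid) of
#'   codon character vectors, with attributes `bias` and `fractions`.
#' @examples
#' m <- codon_usage_mouse()
#' allowed_codons(m, bias = 0.2)$A
#' @export
allowed_codons <- function(table, bias) {
  stopifnot(inherits(table, "codon_usage"))
  if (!is.numeric(bias) || length(bias) != 1L || is.na(bias) ||
      bias < 0 || bias > 1)
    stop("bias must be a single number in [0, 1]", call. = FALSE)
  fallback <- character(0)
  split_tab <- split(table, table$amino_acid)
  map <- lapply(split_tab, function(d) {
    d <- d[order(-d$family_fraction, d$codon), ]
    keep <- d$family_fraction >= bias
    if (!any(keep)) {
      keep[1] <- TRUE
      fallback <<- c(fallback, d$amino_acid[1])
    }
    setNames(d$family_fraction[keep], d$codon[keep])
  })
  if (length(fallback))
    warning("bias ", bias, " excludes every codon for: ",
            paste(fallback, collapse = ", "),
            "; retaining the most abundant codon", call. = FALSE)
  structure(lapply(map, names), bias = bias, fractions = map,
            class = "allowed_codon_map")
}

#' @export
print.allowed_codon_map <- function(x, ...) {
  cat(sprintf("allowed_codon_map (bias = %g): %d amino acids, %d codons\n",
              attr(x, "bias"), length(x), sum(lengths(x))))
  invisible(x)
}

#' Back-translate a protein with the most abundant allowed codons
#'
#' Greedy most-abundant-codon back-translation; the usual codon-optimization
#' baseline that diversification is compared against.  A terminal stop on the
#' protein is emitted as `TAA`.
#'
#' @param protein a [protein_sequence()] or string.
#' @param allowed an `allowed_codon_map` from [allowed_codons()].
#' @param name label for the output.
#' @return a [coding_sequence()].
#' @export
back_translate <- function(protein, allowed, name = "") {
  p <- .as_protein(protein)
  stopifnot(inherits(allowed, "allowed_codon_map"))
  res <- strsplit(p$seq, "")[[1]]
  codons <- vapply(res, function(a) allowed[[a]][1], character(1))
  s <- paste(codons, collapse = "")
  if (p$has_stop) s <- paste0(s, "TAA")
  coding_sequence(s, name = name)
}
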