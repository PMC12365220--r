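# Internal string/DNA helpers.  Coordinates are 0-based half-open internally;
# writers emit 1-based closed coordinates.

.dna_norm <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !is.character(x))
    stop(what, " must be a single character string", call. = FALSE)
  s <- chartr("u", "t", x)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  if (nchar(s) > 0L && grepl("[^ACGT]", s))
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  s
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# extract the raw DNA string from a coding_sequence or plain character
.as_dna <- function(x, what = "sequence") {
  if (inherits(x, "coding_sequence")) return(x$seq)
  .dna_norm(x, what)
}

.as_protein <- function(x) {
  if (inherits(x, "protein_sequence")) return(x)
  if (inherits(x, "coding_sequence")) return(translate_cds(x))
  protein_sequence(x)
}

# evaluate expr under a fixed RNG state without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# tiny polynomial rolling digest used to fingerprint parameter sets in reports
.params_digest <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a multi-record FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a named
#' character vector of uppercase DNA strings.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to FASTA
#'
#' Records are wrapped at 60 columns.
#'
#' @param seqs named character vector (or list of `coding_sequence`) to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs))
    seqs <- vapply(seqs, function(s) if (inherits(s, "coding_sequence")) s$seq else s,
                   character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(ss))) names(ss) <- paste0("seq", seq_along(ss))
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}
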