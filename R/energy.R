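# The repeat-interaction objective f: Boltzmann-weighted aggregation of
# duplex stacking energies over all maximal exact repeats of a construct,
# accumulated in log space so the >1e308 regime never overflows machine
# arithmetic.

#' Unified nearest-neighbor stacking free energies
#'
#' Watson-Crick nearest-neighbor stacking free energies (dG at 37 degrees C,
#' kcal/mol) for all 16 dinucleotide stacks, expanded from the 10 unique
#' unified NN parameters by reverse-complement symmetry.
#'
#' @return named numeric vector of length 16 (names `AA` ... `TT`).
#' @export
nn_stack_delta_g <- function() {
  c(AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88,
    CA = -1.45, CC = -1.84, CG = -2.17, CT = -1.28,
    GA = -1.30, GC = -2.24, GG = -1.84, GT = -1.44,
    TA = -0.58, TC = -1.30, TG = -1.45, TT = -1.00)
}

.stack_vector <- function(nn_table) {
  bases <- c("A", "C", "G", "T")
  all16 <- as.vector(t(outer(bases, bases, paste0)))  # AA, AC, ..., TT
  miss <- setdiff(all16, names(nn_table))
  if (length(miss))
    stop("nn_table must cover all 16 dinucleotide stacks; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  unname(nn_table[all16])
}

#' Energy-model parameters for the objective f
#'
#' @param window probe window length (bp) for window-level duplex queries
#'   ([duplex_delta_g()]).
#' @param min_match minimum exact-match length (bp) for a duplex to count as
#'   interacting; shorter shared stretches are treated as thermally unstable
#'   and contribute nothing.
#' @param temperature Kelvin; sets `RT = 0.0019872 * temperature` kcal/mol.
#' @param nn_table named vector of stacking free energies covering all 16
#'   dinucleotide stacks (kcal/mol).
#' @param init_dg duplex initiation free-energy penalty (kcal/mol) added to
#'   every repeat's dG in the objective (standard unified nearest-neighbor
#'   initiation, two helix termini).
#' @param overflow_log10 log10 threshold above which a score is flagged as
#'   exceeding double-precision range (default 308).
#' @return an object of class `energy_params`.
#' @export
energy_params <- function(window = 16L, min_match = 8L, temperature = 310.15,
                          nn_table = nn_stack_delta_g(), init_dg = 1.96,
                          overflow_log10 = 308) {
  window <- as.integer(window); min_match <- as.integer(min_match)
  if (is.na(min_match) || min_match < 2L) stop("min_match must be >= 2", call. = FALSE)
  if (is.na(window) || window < min_match)
    stop("window must be >= min_match", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  stacks <- .stack_vector(nn_table)
  if (!is.numeric(init_dg) || length(init_dg) != 1L || is.na(init_dg))
    stop("init_dg must be a single number", call. = FALSE)
  structure(list(window = window, min_match = min_match,
                 temperature = temperature, rt = 0.0019872 * temperature,
                 nn_table = nn_table, stacks = stacks, init_dg = init_dg,
                 overflow_log10 = overflow_log10),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf("energy_params: window %d bp, min match %d bp, T = %.2f K (RT = %.4f kcal/mol)\n",
              x$window, x$min_match, x$temperature, x$rt))
  invisible(x)
}

.fscore <- function(log10_f, params) {
  overflowed <- is.finite(log10_f) && log10_f > params$overflow_log10
  structure(list(log10_f = log10_f, overflowed = overflowed,
                 f_capped = 10^min(log10_f, params$overflow_log10),
                 overflow_log10 = params$overflow_log10),
            class = "fscore")
}

#' @export
print.fscore <- function(x, ...) {
  if (!is.finite(x$log10_f) && x$log10_f < 0)
    cat("f score: no interacting subsequence pair (sentinel)\n")
  else
    cat(sprintf("f score: log10 f = %.3f%s\n", x$log10_f,
                if (x$overflowed) sprintf(" (> 1e%d, overflow regime)",
                                          as.integer(x$overflow_log10)) else ""))
  invisible(x)
}

#' @export
format.fscore <- function(x, ...) {
  if (!is.finite(x$log10_f) && x$log10_f < 0) "-Inf (no interactions)"
  else sprintf("1e%.2f%s", x$log10_f, if (x$overflowed) " [overflow]" else "")
}

#' Duplex interaction energy of two windows
#'
#' Locates the longest exact match between the two windows (ties resolved in
#' favor of the most negative energy) and returns the nearest-neighbor
#' stacking free-energy sum over that matched run; `NA` when the longest
#' match is shorter than `min_match`.
#'
#' @param win_a,win_b DNA strings of length `params$window`.
#' @param params an [energy_params()] object.
#' @return dG in kcal/mol (more negative = stronger), or `NA_real_`.
#' @export
duplex_delta_g <- function(win_a, win_b, params = energy_params()) {
  win_a <- .as_dna(win_a, "win_a"); win_b <- .as_dna(win_b, "win_b")
  if (nchar(win_a) != params$window || nchar(win_b) != params$window)
    stop("both windows must have length params$window = ", params$window,
         call. = FALSE)
  r <- cpp_duplex(win_a, win_b, params$stacks, params$min_match)
  if (is.null(r$delta_g)) NA_real_ else r$delta_g
}

#' Repeat-interaction objective f of a construct
#'
#' Forms `C = context || seq` and aggregates, over every maximal exact repeat
#' of `C` of length at least `params$min_match` whose later copy involves
#' `seq`, the Boltzmann weight `exp(-dG/RT)` of the duplex formed by the two
#' copies (`dG` = nearest-neighbor stacking sum over the matched run).  The
#' sum is accumulated by log-sum-exp and reported as `log10 f`; a construct
#' with no qualifying repeat gets the `-Inf` sentinel.  Scores above
#' `overflow_log10` (default 308, the double-precision decimal range) are
#' flagged `overflowed`.
#'
#' @param seq the designed/query sequence ([coding_sequence()] or DNA string).
#' @param context optional fixed reference context prepended to `seq`;
#'   repeats internal to the context are not counted.
#' @param params an [energy_params()] object.
#' @return an `fscore` object: `log10_f`, `overflowed`, `f_capped`.
#' @export
objective_f <- function(seq, context = NULL, params = energy_params()) {
  s <- .as_dna(seq, "seq")
  if (nchar(s) == 0L) stop("seq must be non-empty", call. = FALSE)
  ctx <- if (is.null(context) || !nzchar(context)) "" else .as_dna(context, "context")
  r <- cpp_objective(s, ctx, params$stacks, params$rt, params$init_dg,
                     params$min_match)
  sc <- .fscore(r$log10_f, params)
  sc$max_run <- r$max_run
  sc$n_interactions <- r$n_runs
  sc
}

#' Objective f of a donor/acceptor pair
#'
#' `pair_f(donor, acceptor)` is `objective_f(acceptor, context = donor)`:
#' donor-to-acceptor and acceptor-internal repeats are counted,
#' donor-internal repeats are not (fixed-context semantics).
#'
#' @param donor,acceptor DNA strings or [coding_sequence()] objects.
#' @param params an [energy_params()] object.
#' @return an `fscore` object.
#' @examples
#' p <- energy_params()
#' pair_f("ACGTACGTACGT", "ACGTACGTACGT", p)$overflowed
#' @export
pair_f <- function(donor, acceptor, params = energy_params()) {
  d <- .as_dna(donor, "donor"); a <- .as_dna(acceptor, "acceptor")
  if (nchar(d) == 0L || nchar(a) == 0L)
    stop("donor and acceptor must be non-empty", call. = FALSE)
  objective_f(a, context = d, params = params)
}

#' Write an f-score report as JSON
#'
#' Emits `{log10_f, overflowed, f_capped, params_digest}`; the `-Inf`
#' sentinel is serialized as `null`.
#'
#' @param score an `fscore` object.
#' @param params the [energy_params()] used (fingerprinted in the report).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_json <- function(score, params, path) {
  x <- list(log10_f = if (is.finite(score$log10_f)) score$log10_f else NULL,
            overflowed = score$overflowed,
            f_capped = score$f_capped,
            params_digest = .params_digest(params[c("window", "min_match",
                                                    "temperature", "init_dg",
                                                    "stacks")]))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
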