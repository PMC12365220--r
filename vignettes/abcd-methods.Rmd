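---
title: "Abundance-biased codon diversification: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-biased codon diversification: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcd)
```

## The problem

Constructs that carry two highly similar coding sequences — most prominently
FRET sensors built on a CFP/YFP pair, which share well above 90% nucleotide
identity because both fluorophores descend from the same ancestral gene —
recombine during viral-vector production and PCR. The recombination product
is a mixture of single fluorescent proteins instead of the sensor, which
destroys quantitative imaging. Because recombination requires long identical
stretches, the remedy is to re-encode one of the proteins with synonymous
codons so that, at the nucleotide level, it shares as little as possible with
the other — while still using codons that are abundant in the expression host,
so that translation is not impaired. That combination is abundance-biased
codon diversification (ABCD): codon choice is restricted to codons whose
within-family usage fraction is at least a user-chosen *bias*, and within that
restriction the sequence is optimized to minimize a repeat-interaction
objective *f* against a reference context.

## The objective *f*

For a construct `C = context || seq`, `objective_f()` enumerates every
maximal exact repeat of `C` (a pair of identical substrings that cannot be
extended on either side) whose later copy involves the designed sequence, and
aggregates their duplex stabilities as Boltzmann weights:

\[
f \;=\; \sum_{r} \exp\!\left(-\Delta G_r / RT\right), \qquad
\Delta G_r \;=\; \Delta G_{\mathrm{init}} + \sum_{\text{stacks in } r} \Delta G^{\circ}_{37}
\]

where the stack energies are the 16 unified Watson–Crick nearest-neighbor
parameters (`nn_stack_delta_g()`), \(\Delta G_{\mathrm{init}} = +1.96\)
kcal/mol is the standard duplex-initiation penalty (two helix termini), and
\(RT = 0.0019872 \cdot T\) with \(T = 310.15\) K by default. The sum is
accumulated with log-sum-exp and reported as \(\log_{10} f\), so the
arithmetic never overflows even when *f* itself exceeds the double-precision
range (`overflow_log10 = 308` flags that regime). A construct with no
qualifying repeat gets a \(-\infty\) sentinel, serialized as `null` in
reports.

Two aggregation choices deserve justification:

* **Repeats, not fixed windows.** Each maximal repeat contributes once, with
  an energy that grows with its full length. A fixed-window formulation caps
  every contribution at the window's stack budget, which makes all scores of
  realistic constructs collapse into a narrow band; run-length scaling is what
  separates a diversified pair (runs of at most ~9 bp, \(f \lesssim 10^7\))
  from a CFP/YFP-like pair (runs of hundreds of bp, *f* far beyond \(10^{308}\))
  by hundreds of orders of magnitude, the behavior the method's diagnostics
  rely on. The window length `window` is still a model parameter: it defines
  the probe length for window-level duplex queries (`duplex_delta_g()`), which
  report the bare stacking sum of the longest shared substring of two windows
  (ties broken toward the most negative energy), gated by `min_match`.
* **`min_match = 8` bp.** Any two unrelated ~700-bp coding sequences share
  hundreds of 6-mers by chance alone; counting them would put a floor of
  roughly \(10^{7}\)–\(10^{8}\) under *every* pair and no design could
  distinguish itself. Eight base pairs is the shortest repeat whose duplex is
  appreciably stable at 37 °C under the parameterization above and is the
  scale at which chance collisions become design-avoidable, so shorter shared
  stretches are treated as noise. With this floor, diversified sequences reach
  \(\log_{10} f\) between \(-\infty\) and ~6, natural cross-organism pairs
  (~55% identity) sit around \(10^{7}\)–\(10^{13}\), and pairs above 95%
  identity overflow — the three regimes the diagnostics are designed to
  separate. Exact numerical parity with other published *f* implementations
  would additionally require their (unpublished) parameter values; the
  ordering of regimes, not the absolute numbers, is what this package's
  checks assert.

`pair_f(donor, acceptor)` is `objective_f(acceptor, context = donor)`:
donor-internal repeats are excluded, donor–acceptor and acceptor-internal
repeats are counted. This fixed-context convention lets a library sequence be
diversified once against its own canonical coding sequence and then be paired
with any donor.

## The search

`diversify()` optimizes codon choice in two phases, both deterministic given
the task seed:

1. **Greedy construction.** Codons are chosen left to right; each candidate is
   scored with the exact objective of the reference context plus the built
   prefix, with ties broken by higher family fraction and then alphabetically.
   Forbidden-motif conflicts (including motifs spanning the context/output
   junction, on both strands by default) trigger bounded backtracking; if a
   motif cannot be avoided the search aborts naming the motif and position.
2. **Simulated annealing.** Random synonymous swaps under a geometric cooling
   schedule (phases restart from the incumbent best). Every move is rescored
   exactly — the repeat scanner is O(n) via seeded k-mer buckets, so a full
   rescore of a ~1.5 kb construct costs microseconds and no incremental
   bookkeeping is needed. Half of the proposals target a codon inside the
   currently dominant repeat (the term that owns the log-sum), which is the
   only move class that can lower the objective once the background is clean.

The `budget` parameter is the total number of annealing iterations; the
default of 200,000 is sized so that a 239-residue (717 bp) target against an
equally long reference converges well inside its plateau in a few seconds on
one core. Budgets of a few thousand already satisfy every hard constraint
(conservation, bias, motifs) and are used for the high-repetition property
checks; the larger default only buys a lower final *f*.

Chained diversification (`diversify_chain()`) re-runs the same search with
the reference grown by each previous output, so that every output is diverse
from the shared reference and from all earlier outputs.

### A hard floor on multi-copy diversification

Some identity is unavoidable. Methionine and tryptophan have a single codon;
nine amino acids have exactly two, differing only at the wobble position; and
most families share their first two bases. A tripeptide like Trp–Asp–Met
therefore admits only two encodings that differ in a single base, and any
*three* mutually diversified copies of a protein containing such a pattern
must — by pigeonhole — share an ~11 bp run in some pair. Uniform random
239-residue proteins contain at least one such pattern more often than not,
so three-way chains typically bottom out at 11 bp rather than below 10, and at
the highest bias a W/M-dense target can hold \(\log_{10} f\) marginally above
7 against a most-abundant-codon reference. This is a property of the genetic
code, not of the search; it mirrors the observation that the hardest
three-fluorophore, high-bias designs retain noticeably longer identical
subsequences than two-sequence designs. Real fluorescent proteins are
tryptophan-poor, which is why published two- and three-way designs can stay
below 10 bp.

## Abundance bias

`allowed_codons(table, bias)` keeps, per amino acid, the codons whose
within-family usage fraction is at least `bias` ("relative abundance" is read
as the within-family fraction — a bias of 20% is only meaningful on that
scale). If a family has no codon at or above the bias, its single most
abundant codon is retained (with a warning), so every protein stays encodable
at any bias in [0, 1]. The bundled murine table
(`codon_usage_mouse()`) is a representative table assembled from commonly
cited usage statistics rather than a verbatim database download; it ships as
plain TSV (`extdata/codon_usage_mouse_synthetic.tsv`) and any organism's
table can be supplied in the same 4-column dialect or as Kazusa-style text.

## Repeat diagnostics

`longest_common_substring()`, `maximal_exact_matches()` and
`dotplot_matches()` audit a sequence pair. The identical-subsequence length
distribution is the histogram of maximal exact match (MEM) lengths: MEMs
avoid double-counting nested substrings and their maximum reproduces the
longest-identical-stretch statistic. The dot plot at word size *k* is exactly
the *k*-window expansion of the MEMs of length at least *k*; forward-only
scanning is the default (recombination acts on same-sense repeats), with a
both-strand mode for motif work. All three are implemented as diagonal scans
in C++; their correctness is defined — and tested — against quadratic
dynamic-programming oracles, not against the implementation.

## Recombination profiling from long reads

The chimera module reimplements the read-level analysis of recombined vector
pools. Reads are kept when both anchors (expected stretches downstream of the
forward and upstream of the reverse primer site) match exactly once within a
Hamming budget, trying the reverse complement when forward matching fails;
the insert between the anchors is extracted and identical inserts are grouped
and counted. Groups at the single-FP reference length are lettered `C`/`Y` at
every position where donor and acceptor differ; a base matching neither is
treated as a sequencing error and discards the whole group. The
count-weighted fraction of `Y` calls at a position estimates the fraction of
molecules recombined before it; a least-squares line summarizes the profile
(linear, with slope 1/span, when breakpoints are equally likely everywhere),
and the fraction of anchored inserts at single-FP length estimates the
recombined fraction of the pool. A non-recombined control pool calibrates a
per-position error floor (its maximum fraction), reported alongside
floor-subtracted values clamped at zero. Groups whose length differs from the
reference are counted in the recombined-fraction denominator but excluded
from position calling — indel-bearing reads cannot be positionally called
without alignment, which is out of scope. Circularly permuted acceptors break
positional colinearity and are likewise out of scope.

`simulate_chimeric_reads()` provides the matching generator: with probability
`rho` a read is a chimera `donor[0:b] || acceptor[b:n]` with `b` drawn over
the discriminating span (uniform by default, custom weights allowed),
otherwise the full construct; inserts are wrapped in the anchors plus short
random flanks, substitution errors are applied i.i.d., and a truth table
records every read's class and breakpoint. It emulates substitution noise and
orientation only — no indels, no quality-dependent errors, no chimeric
artifacts of library preparation — so pipeline tests against it demonstrate
estimator correctness under the stated model, not robustness to every
nanopore artifact.

## Synthetic homolog pairs

`make_homolog_pair()` generates the test bed for all of the above: a random
protein and two coding sequences at a target nucleotide identity. At identity
0.90 and above the edits are confined to mutation hotspots in the first ~35%
and last ~12% of the gene — fluorescent-protein variants differ at a handful
of clustered codons, which is precisely why they retain identical stretches of
hundreds of base pairs at 95–97% identity — so the central portion of the pair
stays identical and the pair lands in the overflow regime. Below 0.90 the
edits are spread uniformly (a cross-organism pair). Synonymous edits are used
before conservative residue swaps, keeping translations near-identical at high
identity. The generator does not emulate phylogeny, codon-usage drift between
organisms, or indels.

## Numerical and interface conventions

* Coordinates are 0-based half-open in every function return; TSV writers
  emit 1-based positions for human consumption.
* The \(-\infty\) sentinel means "no interacting pair"; `f_capped`
  saturates at `10^overflow_log10` so downstream consumers never see `Inf`.
* Equal-score codon candidates are ordered by family fraction, then
  alphabetically; all stochastic draws derive from one seed (a
  platform-independent generator on the C++ side, R's RNG — restored after
  use — on the simulator side), so every run is bit-reproducible.
* Degenerate inputs: sequences shorter than `min_match` simply score the
  sentinel (a single-residue target is legal and forced); a target carrying a
  terminal stop codon has it copied verbatim and excluded from the search;
  an empty protein, out-of-range bias, or non-ACGT input is an error.
* Problem sizes in the shipped checks: substring statistics are verified
  against quadratic oracles on 500 random pairs up to 200 bp and the
  objective against exhaustive enumeration on 60-bp pairs (to 1e-9 in
  \(\log_{10}\)); constraint properties on 1,000 seeded runs at 50–300
  residues with a reduced annealing budget; the bias sweep and three-way
  chain at the full 239-residue, 200,000-iteration scale; the read-level
  pipeline at 10,000 reads.

## Known limitations

* The objective counts exact repeats only; near-identical stretches with
  scattered mismatches (which can still recombine) are invisible to *f*,
  though they shorten as a side effect of exact-repeat removal.
* mRNA secondary structure, codon-pair bias and melting-temperature
  calculations are out of scope; the bias floor is the only expression
  safeguard.
* The multi-copy pigeonhole floor above: three-way designs of
  tryptophan/methionine-rich proteins cannot go below ~11 bp shared runs.
* Anchor matching is substitution-only; reads whose anchors carry indels are
  dropped rather than rescued by alignment.
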