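---
title: "Alignment-free assembly finishing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free assembly finishing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomfinish)
```

# The problem

Long-read assemblers produce drafts whose large-scale structure is usually
right but whose base-level accuracy is limited by the raw read error
profile: scattered substitutions, abundant small indels (the dominant error
mode of nanopore data), and unresolved regions written as runs of `N`.
Polishing with short accurate reads normally means aligning the reads to
the draft, which is the most expensive step of the whole workflow.

`bloomfinish` implements the alignment-free alternative: reduce the short
reads to their k-mer content once, store it in a probabilistic membership
structure, and then ask, for every position of the draft, *do the k-mers
covering this base exist in the reads?* A base covered by absent k-mers is
wrong or lies next to something wrong; a candidate correction is good if it
restores membership. Reads are never aligned, only hashed.

# The k-mer evidence structure

## Cascading Bloom filters

A Bloom filter stores a set of canonical k-mers (the lexicographic minimum
of a k-mer and its reverse complement, so membership is strand-insensitive)
in `m` bits with `h` hash functions. It never forgets an inserted element
(no false negatives) and answers false positives at the analytic rate

```
f = (1 - exp(-h * n / m))^h
```

Raw read k-mers are dominated by singletons created by sequencing errors:
an error in the middle of a read corrupts k consecutive k-mers, each of
which is usually unique. `build_cascading_filter()` therefore streams the
reads through two equal filters: an occurrence already present in level 1
is inserted into level 2. Level 2 — the only filter kept — contains every
k-mer of true multiplicity ≥ 2 *exactly* (the no-false-negative guarantee
survives the cascade) plus a bounded trickle of singletons admitted by
level-1 false positives. At 30× coverage, genuine genomic k-mers appear
tens of times while error k-mers appear once, so multiplicity ≥ 2 is a
cheap and effective error filter.

## Sizing

`optimal_bits(n, f)` inverts the rate relation at `h = 1`:
`m = ceiling(-n / log(1 - f))`. The element count `n` that matters is the
number of *repeated* k-mers, `n = F0 - f1` (distinct k-mers minus
singletons), which `kmer_spectrum()` computes exactly with a hash map —
streaming cardinality estimators trade accuracy for memory that desk-scale
and bacterial-scale data do not need. For a 30× human short-read set at
k = 65 the spectrum gives `F0 = 50,900,032` and `f1 = 44,179,082`, hence
`n = 6,720,950` and, at the default target `f = 0.005`:

```{r sizing}
n <- repeated_kmer_count(list(F0 = 50900032, f1 = 44179082))
m <- optimal_bits(n, 0.005)
c(n = n, bits = m, megabytes = bits_to_megabytes(m))
```

One hash function (`h = 1`) is the default because the sizing formula and
the downstream tools assume it; more hashes buy a slightly lower rate at
the same memory but cost proportionally more time per query.

Hashing is a seeded 64-bit FNV-1a with a splitmix64 finalizer. The point is
not hash quality esoterica but *reproducibility*: two runs with the same
seed build bit-identical filters on any platform, which makes the whole
pipeline deterministic (and testable byte-for-byte).

# Polishing

## The scan

`polish_contig()` slides over the contig left to right at one k. A base is
**suspect** when two conditions hold:

1. the k-mer *ending* at it is absent from the filter, and
2. at least `trigger_frac` (default 0.5) of *all* k-mers covering it are
   absent.

Condition 1 anchors the diagnosis to a specific locus — for an isolated
error, the first absent terminal k-mer is exactly the one ending on the bad
base. Condition 2 protects against Bloom false positives and ragged
evidence: a single absent k-mer among 40 present ones is noise, not an
error.

At a suspect base the scanner enumerates every candidate edit: the 3
substitutions, all insertions of 1–5 nt (4 + 16 + … + 1024 = 1364), and
deletions of 1–5 nt — 1372 candidates, in a fixed order (substitutions,
then insertions by length then lexicographically, then deletions by
length). Each candidate is scored by its **support**: the fraction of
k-mers covering the edited locus that are present after applying it. The
best candidate wins if its support reaches `accept_frac` (default 0.5);
ties break by enumeration order, which deliberately prefers the most
parsimonious edit. The search short-circuits at support 1.0, which is
consistent with the tie rule (nothing can beat 1.0, and later ties lose).

When no candidate qualifies the base is **soft-masked** — lowercased, one
base per failure, so consecutive failures form masked runs naturally. The
lowercase channel is the pipeline's hand-off: masked sequence is never
edited again by the polisher and becomes the gap filler's problem.
Symmetrically, existing `N` and lowercase characters are never edited.

Both thresholds default to 0.5 of the covering k-mers. There is no
published numeric value for "sufficient support"; 0.5 is the natural
majority rule, it is recorded in every run header, and the change tables
carry per-edit support so any downstream consumer can re-threshold.

## Resuming after an edit

After an accepted edit the scan resumes at the first base *past* the
edited locus. An earlier design resumed a full k bases later (at the first
k-mer no longer covering the edit), reasoning that this prevents cascading
re-edits. Implementation proved the skip both unnecessary and harmful:

* unnecessary, because a correctly fixed locus cannot re-trigger — its
  terminal k-mer is now present, and condition 1 never fires;
* harmful, because the skip jumps over the second member of any error pair
  closer than k, leaving it unfixed and forcing a masked run. On a 100 kb
  benchmark with ~200 substitutions this cost 7 percentage points of
  reversion (87.7% → 94.6% after the change).

## Why errors can legitimately survive one pass

Three mechanistic classes of injected error are *not* fixed by a single-k
pass, and tests assert this accounting rather than pretending the pass is
perfect:

* **Close pairs.** Two errors `d < k/2` apart: reverting one still leaves
  every covering k-mer of the other absent, so no candidate reaches 50%
  support and both are masked. This is by design — guessing two
  interacting edits from marginal evidence is how mis-polishing happens.
  The masked run is resolved by the gap filler (or by a shorter k whose
  window separates the pair).
* **Contig-end blind spots.** k-mers within a read length of a linear
  contig's end are covered by very few read start positions (the terminal
  k-mer by exactly one), so they rarely reach multiplicity 2 and the
  filter holds no evidence there. The polisher masks what it cannot
  verify.
* **Bloom false-positive skips.** At `f = 0.005`, one terminal k-mer in
  200 looks present when it is not, and the scan walks past the ideal
  locus. The sweep's next k re-examines the locus with an independent
  filter.

## The k sweep

`ksweep_polish()` runs the single-k pass iteratively from the longest k to
the shortest, feeding each output to the next pass. Long k-mers are
specific (a 65-mer rarely repeats) but fragile (one error corrupts 65
windows and low-coverage stretches lose them); short k-mers are robust but
ambiguous in repeats. Sweeping long to short fixes the confidently
fixable first and lets shorter k recover what longer k could not evidence.
Masks only accumulate across iterations — a locus no k would touch stays
masked, and the per-k change tables (`.k<k>_changes.tsv`) record every
applied edit with 1-based positions on that iteration's input, so each
stage replays exactly.

# Between polishing and gap filling: consolidation

A masked run flanked by a handful of confident bases flanked by another
masked run is one problem, not three: no k-mer of the sweep's smallest k
fits inside an island shorter than `k_min`, so the island's "confidence"
is unverifiable. `consolidate_mask()` lowercases every maximal uppercase
run shorter than `k_min` whose immediate neighbours are both soft runs,
re-evaluating to a fixpoint so chains of islands merge. Sequence ends and
`N` runs do not count as masking flanks — a terminal island or one beside
a hard gap is kept, because there the island is the only anchor available.

# Gap filling

`ksweep_fill()` treats both `N` runs and soft-masked runs as gaps
(adjacent runs merge, hard beats soft). For each gap it extracts clean
(uppercase ACGT) flanks of up to `flank_len = 100` nt, and runs a bounded
depth-first traversal of the implicit de Bruijn graph: starting from the
terminal k-mer of the left flank, extend one base at a time through k-mers
present in the filter until the first k-mer of the right flank appears.

The numerical guards and their rationale:

* `max_len = gap + 2 * slack` (slack 100): the true fill should be about
  the gap's length; the allowance absorbs gap-length misestimates without
  letting the search wander.
* `max_branches = 10000` expansions per gap: the budget that keeps a
  repeat tangle from consuming the run.
* `max_paths = 2` with **unanimity**: the searcher stops after two
  successful paths; a fill is accepted only if every collected path is the
  same sequence. One path = unique reconstruction; two different paths =
  genuinely ambiguous locus, better left open than guessed. Unfilled soft
  gaps are restored to uppercase at the end (their pre-masking sequence is
  the best remaining estimate), while unfilled hard gaps stay `N`.
* k below 40 triggers a warning: the traversal's branching factor rises
  steeply as k shrinks, and 40 is the practical floor for filling.

Fills are spliced in uppercase, right-to-left within each contig so earlier
gap coordinates stay valid.

# The pipeline

`run_finish()` chains the stages — filters, polish sweep, consolidation,
gap-fill sweep — building one filter per k and sharing it between the
polisher and the filler. Every stage's output is written before the next
begins (`.ntedit_edited.fa`, `.ntedit_edited.prepd.fa`,
`.ntedit_edited.prepd.sealer_scaffold.fa`, plus per-k change tables, a gap
log and a run-info header), so a crash leaves the completed prefix of the
protocol on disk and every parameter of the run is recorded.

# The synthetic benchmark

The package carries its own truth-known benchmark
(`synthetic_fixture()`): a 100 kb uniform random genome; a draft carrying
0.2% substitutions and 0.02% indels of 1–5 nt (point events kept ≥ 10 nt
apart so each has a well-defined truth), three disjoint 100 nt `N` gaps
placed ≥ 500 nt from each other and from the ends (so gap flanks are
clean); and error-free 150 bp reads at 30× drawn uniformly from both
strands. Sub-seeds are derived from one master seed, so the whole fixture
is reproducible byte-for-byte.

Scope and limits, stated plainly:

* A uniform random genome has almost no repeats, so it measures the
  *mechanism* (detection, correction, traversal), not repeat resolution.
  Real genomes will mask more and fill less.
* Error-free reads isolate the draft's errors from read errors. The
  cascading filter is the component that absorbs read errors, and it is
  tested separately against brute-force multiplicities.
* Read starts are uniform over a linear sequence, so coverage ramps down
  over the terminal read length — the contig-end blind spot described
  above is a *property of the data*, and the evaluator sees it.

Scoring uses two independent instruments: `score_reversion()` checks each
injected event's ±25 nt truth context for verbatim occurrence in the
polished sequence (on a random genome a 51-mer is effectively unique), and
`evaluate_assembly()` computes an exact banded global alignment against
the truth (the band doubles until the optimum is interior, so narrowness
never biases the result) reporting mismatches and indel *events* per
100 kbp, in the style of standard assembly QC.

On the standard fixture the full pipeline reverts 100% of injected point
errors, closes all three gaps with fills identical to the truth, and
returns a final sequence byte-identical to the truth genome in under a
minute on one CPU.

# Defaults at a glance

| Parameter | Default | Why |
|---|---|---|
| `h` | 1 | sizing formula and query speed assume it |
| `f` target | 0.005 | published operating point; 1 spurious query in 200 |
| `trigger_frac` | 0.5 | majority of covering k-mers must be absent |
| `accept_frac` | 0.5 | majority of covering k-mers must be restored |
| `max_indel` | 5 | covers the dominant small-indel error mode |
| `flank_len` | 100 | two read-halves of anchor on each side |
| `slack` | 100 | tolerated fill-length deviation per side |
| `max_branches` | 10000 | abort budget for repeat tangles |
| `max_paths` | 2 | unanimity check; more paths cost time, not safety |
| `seed` | 13 | fixed so identical runs are byte-identical |
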