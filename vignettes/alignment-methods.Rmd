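---
title: "Methods: FM-index search, the Suffix Tarray, and lower-bound pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FM-index search, the Suffix Tarray, and lower-bound pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staligner)
```

## The problem

Short-read alignment maps millions of ~100 bp DNA reads onto a reference
genome, tolerating a bounded number of differences (sequencing errors and
true variants). The dominant family of tools performs *backward search* over
the Burrows–Wheeler transform (BWT) of the reference: a query is consumed
from its last base to its first, and at every step the set of matching
reference suffixes is a contiguous block `[k, l]` of suffix-array rows whose
width is the occurrence count. `staligner` implements this machinery at desk
scale, together with two speed-oriented refinements: a truncated suffix-trie
cache over the index (the *Suffix Tarray*) and a tightened per-prefix lower
bound on edit cost used to prune the inexact search.

## The FM-index core

A single sentinel, lexicographically smaller than every base, terminates the
text; rows are 0-based over `n + 1` suffixes and row 0 is always the sentinel
suffix. The interval of the empty query is `[0, n]` — all rows, including the
sentinel row. (Conventions that exclude row 0 from the empty-query interval
silently lose matches ending at the last text position: the row of the
suffix `c$` is skipped by `Occ(c, 0)` whenever the text ends in `c`. The
inclusive convention is the one under which every printed example in this
package's tests checks out.)

Backward extension uses the classic update
`k' = C(c) + Occ(c, k - 1)`, `l' = C(c) + Occ(c, l) - 1`, where `C(c)` counts
text characters smaller than `c` and `Occ(c, y)` counts `c` among the first
`y + 1` BWT characters. `Occ` is answered from a bucket table plus an
in-bucket scan; `bucket_size` (default 128) and the suffix-array
`sample_rate` (default 4, text-position sampling, so a locate walk-back is
at most `sample_rate - 1` LF steps) affect speed and memory only — the test
suite asserts identical results across bucket sizes 1, 64 and `n + 1` and
across sample rates.

Ambiguous reference bases (`N`) are replaced by a base chosen by a
deterministic integer hash of the position, keeping the alphabet at four
letters without consuming RNG state; an `N` in a read is coded as a symbol
that matches nothing, i.e. a guaranteed mismatch. Multi-record references are
concatenated with separator symbols that the search never extends through,
so no alignment can span two records.

Suffix arrays are built by prefix doubling (`O(n log^2 n)` with vectorised
radix ordering); correctness, not asymptotics, is the contract at desk
scale, and the builder is checked against brute-force suffix sorting.

## The Suffix Tarray

Backward search spends most of its time in `Occ`. The Suffix Tarray caches
the most frequently visited intervals in a trie laid over the reversed
reference: a root-to-node path, with edges in backward-search consumption
order, is a substring of the reversed reference, and the node stores the SA
interval of the reversed path string on the *forward* index. A node's
frequency — its occurrence count in the reversed reference — equals its
interval width, which is why the trie can be built from the forward index
alone by breadth-first backward extension; no second index is needed.

Nodes with frequency below a threshold `epsilon` are discarded, which keeps
the trie prefix-closed automatically (frequency never increases along a
path). The builder aborts with a size signal as soon as the non-root node
count would exceed the node budget (derived from a byte budget at 36 bytes
per node); `select_epsilon()` binary-searches the smallest admissible
threshold, which by monotonicity yields the *largest* trie within budget.
The narrated alternative — treating the threshold as something to maximise —
contradicts that monotonicity, so the monotone reading is implemented.
Default trie depth cap is 12: desk-scale references saturate far shallower,
and the cap bounds worst-case construction on repetitive text.

During a query the trie is descended while a child edge exists; at the first
missing child the state drops permanently to plain FM extension seeded with
the current interval. The load-bearing property, asserted step-by-step over
thousands of random queries, is that the trie changes *speed only*: every
interval equals the FM-only interval.

## Bounded inexact search

`inexact_search()` runs depth first from the read end toward the start,
branching on match, substitution (cost 1), deletion of a reference base and
insertion of a read base. Gap costs follow the aligner convention the tool
family uses: opening a gap costs one difference, and up to
`max_gap_extensions` consecutive extension columns cost nothing. The
extension rule is applied to insertion runs and deletion runs symmetrically.
Two caps make the search tractable: `max_gap_opens` (default 1; an uncapped
budget-5 search is combinatorially intractable because an insertion branch is
available at every node) and optional seeding (`seed_length`,
`seed_max_diff`): at most `seed_max_diff` charged differences inside the last
`seed_length` bases, the portion searched first. Branch order is
match > substitution > deletion > insertion; the hit *set*, not its order, is
the contract, and hits are deduplicated per SA interval keeping the lowest
difference count.

Mapping quality uses a deliberately simple monotone scheme (the upstream
tools' exact formula is out of scope): 0 for multiple co-optimal placements,
37 for a unique placement with an empty next stratum, otherwise
`max(3, 25 - 3 s)` for `s` competing next-stratum placements. Placements are
counted per *locus* — positions within 5 bp on the same strand collapse —
because an alignment re-parsed with one superfluous edit is not a competing
placement. Qualities at or above 10 are "confident", matching the
evaluator's threshold.

## Lower-bound pruning

Before searching, a per-prefix lower bound `D[i]` on the cost of aligning
`W[1..i]` to *any* reference substring is computed on the index of the
reversed reference; a branch is cut whenever the remaining difference budget
falls below the bound. Two calculators are provided.

**Single-mismatch segmentation** (`calculate_d_basic`): scan the read
keeping a window that must remain an exact reference substring; every break
adds one to the bound and restarts the window empty. For reference
`AACGTATCGACG` and read `AACTGA` this yields `0 0 0 1 1 1`.

**Pattern-tightened bound** (`calculate_d_dcdc`): frequently recurring read
substrings that need exactly two edits against the reference are mined
offline and organised in an Aho–Corasick automaton. During the scan the
automaton runs concurrently with the fallback window; when a pattern
completes at position `i`, `D[i]` becomes the bound at the segment start plus
2, and everything restarts at `i + 1`. Positions before a pattern completes
carry the fallback bound — the only reading consistent with the printed
worked value `0 0 0 1 2 2` for pattern `AACTG`, where `D[4] = 1` comes from
the fallback while the pattern is still pending. A final running maximum
restores monotonicity. With an empty automaton the result is identical to
the basic bound, and property tests certify both bounds against a full
dynamic-programming oracle whenever the recorded pattern edit values are
correct.

Matches fire when the automaton reaches a leaf state directly *or through
its failure chain* (classic output links): the reported pattern is the
longest pattern suffix of the scanned window, the automaton then resets to
the root, and matches are therefore non-overlapping and greedy-first.

**The cost-metric asymmetry.** The search charges gap extensions zero; the
D-arrays charge every column one (otherwise any read would be a single gap
and no bound above 1 could exist). Both bounds are therefore strictly
correct under the D-metric but can exceed the search-metric cost of a gapped
alignment, so pruning can discard alignments the search metric would accept
— and the tightened bound discards slightly more than the basic one. This is
implemented exactly as described, documented as the known source of missed
gapped alignments, and reproduced by a constructed regression case (a
two-gap, two-mismatch alignment of search cost 4 that survives basic
pruning and is cut by a tightened bound of 3 at the critical position).

## Pattern mining

`mine_frequent_patterns()` enumerates substrings of a training read set by
depth-first traversal of an FM-index over their separator-joined
concatenation, with a frequency floor (default 10 occurrences — the source
material names no floor; the value exists to keep sequencing noise out of
the automaton and is deliberately conservative at desk scale). Candidates
with edit value exactly 2 against the reference are accepted in decreasing
frequency (ties lexicographic, for determinism) until the automaton byte
budget — 64 bytes per state, root included — is filled. Whether "two edits"
counts indels is genuinely ambiguous in the source material (its own worked
example is substitution-only); it is exposed as the `model` switch, with
`full_edit` the default and `substitution_only` available.

## Read simulation and scoring

`simulate_reads()` draws uniform start positions (records weighted by
length), a random strand, independent per-base substitution errors at
`error_rate` (default 2%, the conventional benchmark figure), and optional
1–3 bp indels at `indel_rate` per read (off by default: the benchmark error
figure is a substitution rate). Truth is encoded in the read name
(`contig_start_strand_serial`, 0-based forward-strand leftmost coordinate),
so third-party aligners can be scored too. The generator reproduces a fixed
seed byte-identically.

What the generator deliberately does **not** emulate: position-dependent
quality profiles, GC bias, duplicated or repetitive genome structure, or
paired-end geometry. A green end-to-end test therefore establishes that the
search machinery recovers planted origins under uniform random error on
random sequence — not performance on a real genome's repeat structure.

`evaluate_alignments()` counts a read correct iff it is mapped at quality
≥ 10, on the true contig and strand, within 5 bp of the true position (the
wgsim-style convention; the tolerance absorbs small indel-induced shifts).
TPR divides by all input reads, PPV by confidently mapped reads.

## Numerical and degenerate-input choices

* Empty interval canonical form is `c(1L, 0L)`; any `k > l` is empty.
* A character outside `{A,C,G,T}` extends to the empty interval rather than
  erroring (reads may contain `N`).
* `select_epsilon` always succeeds for budgets ≥ 1 because the threshold `n`
  admits at most the single-character nodes of a uniform text.
* Duplicate mined patterns collapse to one automaton leaf; an empty pattern
  set yields a root-only automaton that never matches.
* Reads shorter than two bases are reported unmapped rather than searched.
* Co-optimal primary-hit tie-break: lowest reference coordinate, forward
  strand first — deterministic output for any input.
* Index serialisation is a versioned container that round-trips
  `identical()`-exact.

## Known limitations

Single-threaded, desk scale by design: no succinct bitvector `Occ`, no
external-memory construction, no multi-gigabase genomes, no paired-end
rescue. The mapping-quality scheme is simpler than production callers'.
Pattern mining is exact but enumerative — millions of patterns are out of
scope.
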