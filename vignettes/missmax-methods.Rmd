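---
title: "Per-suffix longest common substrings with mismatches: methods and design"
author: "missmax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-suffix longest common substrings with mismatches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missmax)
```

## The statistic

Given a query $x = x_1 \dots x_n$ and a subject $y = y_1 \dots y_m$ over an
alphabet $\Sigma$, write $X_i$ and $Y_j$ for their suffixes and
$LCP_k(X_i, Y_j)$ for the length of the longest common prefix of the two
suffixes when up to $k$ mismatches (Hamming differences) are tolerated.
The package computes the per-suffix vector

$$\mathrm{MaxCor}_k(i) = \max_{j = 1 \dots m} LCP_k(X_i, Y_j),
  \qquad i = 1 \dots n,$$

from which two classical alignment-free similarity statistics follow at no
extra cost: the *longest* common substring with $k$ mismatches
$\mathrm{MaxCor}_k = \max_i \mathrm{MaxCor}_k(i)$ (the $k$-mismatch longest
common factor), and the *average*
$k\mathrm{ACS} = \frac1n \sum_i \mathrm{MaxCor}_k(i)$, the $k$-mismatch
generalization of the average common substring measure used for
alignment-free phylogenetics.

Match semantics are strict: two residues match iff they are equal and
in-alphabet.  Ambiguity codes (N, IUPAC degeneracies) are encoded as a
sentinel that matches nothing, including another sentinel, so undefined
regions always burn mismatch budget.  This deliberately prevents the
pathology where an N-run in one genome ties *every* position of the other
at exact-match length zero; soft-masking (lower case) carries no meaning
here and input is simply upper-cased, because the statistic has no masking
concept.

## The exact algorithm

A naive computation evaluates $LCP_k$ for all $n \cdot m$ pairs
(`naive_maxcor()`, kept as the reference oracle).  The filtered algorithm
(`maxcor_vector()`) solves suffix 1 by a full sweep of $m$ jump-extensions
— $k+1$ chained exact extensions, each skipping one mismatch — and then
derives each step $i+1$ from step $i$, which carries its optimum
$L = \mathrm{MaxCor}_k(i)$ and the list of *all* $y$-positions attaining it
(the ties).

**Carry-over.**  Every tie $j$ yields a candidate at $j+1$: if
$x_i = y_j$ the $k$ mismatches lie strictly inside the old window and the
pair $(i{+}1, j{+}1)$ attains exactly $L-1$; if $x_i \ne y_j$ the leading
mismatch is released, the old window's final mismatch is absorbed, and the
pair attains $L + LCP_0(X_{i+L+1}, Y_{j+L+1})$ — one cheap exact extension.
When the step-$i$ alignment already touched a sequence end the presupposed
final mismatch does not exist and the candidate is recomputed directly with
one $LCP_k$ call.  Ties at $j = m$ have no image; if none survives the step
falls back to a full sweep.  The carried maximum $L_{max}$ is never below
$L - 1$.

**Filtering.**  Any other position $r$ satisfied
$LCP_k(X_i, Y_r) < L$ (strictly, because the tie list is complete), which
yields two per-symbol filters for the pair $(i{+}1, r{+}1)$: (a) if
$y_r = x_i$ the pair attains at most $L-2$ and is discarded; (b) any match
of length $\ge L$ must run *exactly* through offset $L$, so $y_{r+L}$ must
equal the anchor $x_{i+L}$.  Both are bit-mask operations over per-symbol
occurrence masks of $y$ built once per comparison.  Survivors are verified
in ascending order: the optimistic length $c = L + LCP_0$ past the anchor
is compared with the running $L_{max}$ (a shortfall rejects the candidate
with no further work), and otherwise one jump-extension computes the true
length, accepted only when it equals $c$ — a cheaper-looking acceptance of
unverified ties would admit pairs whose window hides an extra mismatch and
break exactness.  An optional whole-segment pre-filter (require
$y[r{+}L .. r{+}L_{max}{-}1]$ to equal $x[i{+}L .. i{+}L_{max}{-}1]$ before
verifying) is available (`segment_filter = TRUE`); it can only discard
candidates that verification would reject, so it never changes results, and
it is off by default.

**The $L-1$ tie pass.**  When a step ends at $L_{max} = L - 1$, filter (b)
is unsound for ties: a pair attaining exactly $L-1$ has its $(k{+}1)$-th
mismatch *at* offset $L$, precisely where the anchor demands a match.  The
exact mode therefore re-scans every position passing filter (a) alone (not
already carried or accepted) with a direct $LCP_k$, completing the tie
list.  This pass is what makes the tie list — and hence every later
carry — complete, and it dominates the cost of exact mode.

**Boundary handling.**  The carry shift $r \mapsto r+1$ can never propose
$y$-position 1, whose extension is unconstrained by step $i$ and can exceed
$L_{max}$ (e.g. `x = "CAAAA"`, `y = "AAAAT"`, $k = 0$: the true
$\mathrm{MaxCor}_0(2) = 4$ is attained only at $j = 1$).  Each step
therefore evaluates the pair $(i{+}1, 1)$ directly with one $LCP_k$ call —
$O(kn)$ in total.  Without this check the stepping scheme is not exact.

The test suite asserts element-wise equality of exact mode with the naive
reference over thousands of random instances (DNA and binary alphabets,
sentinel-bearing inputs, $k$ from 0 to 10, $n$ up to 500), plus soundness
of every mask exclusion against a pure-R prefix-scan oracle written
independently of the compiled code.

## Relaxed mode and the greedy baseline

Relaxed mode (`mode = "relaxed"`) is identical except that the $L-1$ tie
pass is skipped.  Tie lists may then be incomplete, subsequent carries may
start lower, and later values may fall below the truth — but never above
it: every reported value is a genuine $LCP_k$ of some pair, so relaxed
values are element-wise dominated by exact ones.  On uniform random DNA
pairs (n = 2,000, k = 5 or 10, 20 seeds) the mean relative error of
$k\mathrm{ACS}$ is about 0.8 %, at roughly half the exact cost — the same
order as the sub-percent errors observed on real mitochondrial genomes.

The greedy baseline (`greedy_maxcor()`) re-implements, at reference scale,
the kmacs-style heuristic: seed each suffix with its longest *exact* match
(all positions attaining it) and extend only those seeds with $k$
mismatches.  It is a lower bound — the longest exact match need not seed
the longest $k$-mismatch match — and on the same random panels its
$k\mathrm{ACS}$ error (~18 %) exceeds the relaxed error by more than an
order of magnitude, reproducing the qualitative precision ranking.
Its engineering internals (enhanced suffix arrays) are out of scope; naive
scanning is used, which is irrelevant to the precision comparison.

## Filtering-power accounting

`FilterStats` counts, against the $n \cdot m$ ceiling, every pair on which
an extension is actually evaluated: the initial (and any fallback) full
sweep, carry-over extensions (the pure $L-1$ arithmetic of the matching
case evaluates nothing and is not counted), the direct position-1 checks,
scan verifications that reach the jump-extension (optimistic rejections
$c < L_{max}$ cost one exact extension at most and are not counted), and
every tie-pass evaluation.  The scan order is fixed (ascending $r$) so the
counters are reproducible; exact-mode *values* are order-independent, the
counters mildly order-sensitive.

Two structural facts are worth stating because they bound what any
convention can report on uniform random DNA: the per-suffix optimum drops
by exactly 1 on roughly a third of steps (measured ~37 % at 16.5 kbp,
k = 5), and each such step's tie pass examines ~3/4 of all positions
(filter (a) alone).  Exact-mode accounting is therefore dominated by the
tie pass (~43 % of $n \cdot m$ at these conditions; relaxed ~16 %), and
exact mode costs about twice the relaxed wall time, while both modes'
*verification* work stays a small fraction of the quadratic ceiling.

## Distances and trees

From $k\mathrm{ACS}$ the package builds the classical ACS-style distance:
$d'(x \to y) = \log(m)/k\mathrm{ACS}(x \to y) - 2\log(n)/n$ (natural log;
the subtracted term is the self-match expectation, making $d(x,x) = 0$),
symmetrized by averaging both directions.  This normalization is adopted
from the ACS/kmacs lineage; the per-suffix statistic itself does not fix a
distance.  Near-identical short sequences can push the formula slightly
negative; values are clamped at 0.  A direction with $k\mathrm{ACS} = 0$
(no shared in-alphabet residue) has infinite distance, reported as a capped
large value (1000) with a warning so downstream tree builders stay finite.
`distance_matrix()` evaluates all unordered pairs (optionally in parallel —
pairs are independent, so thread count never changes a number),
`write_phylip()`/`read_phylip()` round-trip the square PHYLIP dialect at
six decimals, and `nj_tree()` delegates neighbor joining and Newick
serialization to `ape`.

## The synthetic generator and what the tests do (and do not) show

`random_sequences()` draws i.i.d. uniform residues — the unrelated-sequence
null for this family of statistics, and the regime in which the published
filtering percentages for random inputs were measured.  The fixture of 5
sequences of 16,500 bp mirrors typical mammalian mitochondrial genome
lengths (16,000–17,000 bp).  Real genomes are not i.i.d.: repeats, skewed
composition and homopolymer runs lengthen matches, enlarge tie sets and
shift filtering percentages (published biological rows run a few points
below random ones).  Passing tests therefore certify algorithmic
correctness and the precision ranking of the variants, not distributional
claims about real data; the real-genome workflow is exercised through the
FASTA/PHYLIP/Newick interfaces but no accessioned dataset is bundled.

## Numerical and design choices

* Coordinates are 1-based at every user-facing surface (the compiled core
  is 0-based internally).
* Tie lists are kept ascending; scan order is ascending; both are
  determinism choices, not requirements of the mathematics.
* Extensions are computed by direct character comparison rather than
  suffix-tree LCA or enhanced suffix arrays: at realistic scales the naive
  extension is faster in practice, and it keeps the core free of index
  construction.
* End-of-string never counts as a mismatch; any formula term referencing a
  position past an end contributes 0, and carry formulas switch to a direct
  $LCP_k$ when the previous alignment touched an end.
* Degenerate carries (all ties at $j = m$) fall back to a full sweep for
  that step.
* Problem sizes in the test-suite panels (instances per configuration,
  n up to 500 for oracle equivalence, n = 2,000 for precision panels) were
  chosen so the whole suite runs in minutes on one CPU while still
  exercising every code path; the full-scale 16.5 kbp benchmark runs once.

## A small worked example

```{r example}
x <- encode_sequence("ACGT", "x")
y <- encode_sequence("TACG", "y")
mv <- maxcor_vector(x, y, k = 0)
mv$values
summarize_comparison(mv)
```

## Known limitations

* Worst-case time remains $O(k n m)$; the filters buy practical, not
  asymptotic, gains (sub-quadratic algorithms exist but trade practicality
  for the bound and are out of scope).
* The per-symbol mask layout targets small alphabets (DNA by default); any
  user alphabet is accepted, but very large alphabets dilute filter (b).
* The published percentage tables for position pairs "considered" rest on
  an unstated counting convention; this package documents its convention
  precisely (above) and reports it everywhere, but cross-implementation
  comparisons of those percentages carry that caveat.
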