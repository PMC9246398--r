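---
title: "Local alignment with stored traceback directions and a systolic-array simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local alignment with stored traceback directions and a systolic-array simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swsystolic)
```

## The model

`swsystolic` computes the optimal local alignment of a query sequence
$q = [q_1, \dots, q_N]$ against a database sequence $s = [s_1, \dots, s_M]$
under the Smith-Waterman recurrence with a linear gap penalty.  Writing
$x = H(i-1, j-1)$, $y = H(i-1, j)$ and $v = H(i, j-1)$ for the three
already-known neighbours of a cell, each cell of the
$(M+1) \times (N+1)$ score matrix (row and column 0 are a zero border) is

$$H(i,j) = \max\{\,0,\; x + P(s_i, q_j),\; y - \gamma,\; v - \gamma\,\},$$

where $P$ is the substitution function — a full matrix, or simply
$\alpha$ on a match and $\beta$ on a mismatch — and $\gamma \ge 0$ is the
per-symbol gap cost (a gap opens and extends at the same price: the linear
special case of the affine model; affine gaps with distinct opening and
extension costs are out of scope).  Scores are integers throughout; there
is no floating point anywhere in the recurrence.

The distinctive feature of this implementation is that the forward stage
also fills a **direction matrix** `D`: for every cell it records which
term of the maximum won, as a two-bit code —

| code | meaning | traceback move | alignment column |
|------|---------|----------------|------------------|
| 2 | diagonal won | up-left | $q_j$ over $s_i$ (match or mismatch) |
| 1 | vertical won | up | dash in the query row, $s_i$ consumed |
| 3 | horizontal won | left | $q_j$ consumed, dash in the database row |
| 0 | the zero floor won | stop | — |

Because the path information is pre-organized during the forward pass,
backtracking needs no score arithmetic at all: starting from the
maximum-score cell (tracked during the fill), it reads codes until it
meets a 0.  Four levels fit in exactly two bits, so the whole traceback
state for an $M \times N$ problem costs $2MN$ bits
(`pack_directions()` provides that packed representation), far less than
storing `H` itself, whose entries need a score-dependent width.

### Tie rules and the zero clamp

Ties in the three-way maximum must be broken deterministically for the
direction chain to be well defined.  The rules adopted, applied
identically in the sequential aligner, the C++ fill and the simulator:

* the **diagonal wins every tie** it takes part in
  ($c_d \ge c_y$ and $c_d \ge c_v$ suffice for code 2);
* a **vertical/horizontal tie goes horizontal** (code 3) — the query
  symbol is consumed first;
* the score is clamped at zero and **code 0 is emitted if and only if the
  clamp wins**, so the traceback's `while (code > 0)` loop terminates
  exactly at the boundary of the aligned region.

The second rule is a genuine convention: when $c_y = c_v > c_d$, neither
candidate dominates and either choice yields a co-optimal alignment.  We
fix one (horizontal) and test it explicitly; swapping the inputs therefore
preserves the optimal score always, but is only guaranteed to mirror the
CIGAR (I and D exchanged) when the optimal path is unique.

### Maximum tracking

The running maximum is updated with a strict inequality during the
column-major fill (query symbol outer, database symbol inner), so among
tied maxima the **first in column-major order** — smallest column, then
smallest row — is reported.  When the matrix is entirely zero there is no
aligned region; the maximum is reported at position (1, 1) with value 0 as
a documented convention, and the backtrack returns an empty alignment.
All reported positions are 1-based matrix coordinates: rows index $s$,
columns index $q$.

## The systolic-array simulator

`simulate_forward()` steps a chain of $N$ processing elements (PEs), one
per query symbol, in discrete cycles.  PE $j$ (0-based) owns matrix column
$j+1$ and holds:

* its **previous output register** `Sc` ($= H(i-1, j+1)$),
* a **one-step-delayed copy of the upstream PE's output**
  ($= H(i-1, j)$, the diagonal dependency),
* a **direction memory** of $M$ two-bit words (one per database symbol),
  written exactly once per address during the forward stage and read only
  after the traceback flag is raised,
* a chained **maximum record** (value, row, column).

At cycle $t$ (0-based), PE $j$ computes cell $(i, j+1)$ with
$i = t - j + 1$ whenever $1 \le i \le M$ — an anti-diagonal wavefront: no
cell is computed before its three neighbours, which the trace log can
verify.  The fill of an $M \times N$ matrix takes exactly $M + N - 1$
cycles under this idealized one-cell-per-PE-per-cycle model; register-stage
latencies of real hardware are deliberately not modeled, which is the same
idealization that underlies the peak-throughput formula below.  The array
requires $M \ge N$ (each direction memory holds one word per database
symbol); `simulate_systolic(..., swap = TRUE)` may swap the inputs, and the
command-line tool does so with a logged notice, but the library refuses
silently swapped calls so the caller's intent stays visible.

The maximum record chains down the PEs with one register of delay per
hop, each PE replacing the incoming record only when its own candidate is
strictly better — on equal values the record from the smaller column (then
smaller row) is kept.  By the final cycle the last PE provably holds the
global maximum, and a test asserts it is the *same cell* the sequential
column-major rule selects, including constructed tie cases.

Backtracking walks the memories: a code-2 read decrements both the memory
address and the active PE, code 3 moves one PE back at the same address,
code 1 decrements the address within the PE, and the walk stops on a 0 or
on stepping past PE 0 or address 0.  `backtrack_cycles` charges one cycle
per PE hop needed to carry the start address from the last PE to the
maximum's PE, plus one cycle per memory read (including the terminating 0
read when one occurs).  The hop accounting is our convention — the
hardware description it mirrors is qualitative — and is stated here so the
cycle numbers are interpretable; the alignment itself is required to be
bit-identical to the sequential `backtrack()` result, and the test suite
checks that identity on hundreds of random cases.

Hardware stores only directions, never scores; the simulator additionally
records the scores it computes (`score_record`) purely so that its forward
stage can be compared cell-for-cell with `forward_fill()`.

## Throughput accounting

Two standard forms of the giga-cell-updates-per-second metric are kept
deliberately separate:

* `gcups_from_time(cells, seconds)` $= \mathrm{cells} / \mathrm{seconds}
  \times 10^{-9}$ — *achieved* throughput of a concrete run;
* `gcups_from_frequency(pe, hz)` $= \mathrm{pe} \times \mathrm{hz} \times
  10^{-9}$ — *peak* throughput of an array, since a systolic array updates
  at most one cell per PE per cycle.

They coincide only in the limit $M \gg N$: a full run achieves
$MN / (M + N - 1)$ cells per cycle, which is bounded by $N$ (a tested
invariant).  For example, 128 PEs at a nominal 100 MHz give a peak of
12.8 GCUPS.  The package makes no wall-clock performance claims about the
host; `perf_report()` simply applies whichever formula the caller's inputs
select.

## The synthetic generator and what passing tests show

`generate_sequences(n, m, alphabet, seed)` draws symbols i.i.d. uniformly
over the alphabet — the same kind of randomly generated input used to
validate the design at demonstration scale (128-symbol query against an
8192-symbol database, i.e. $1{,}048{,}576$ cells, with match 5,
mismatch −5, gap 1).  Uniform random sequences exercise every code path —
matches, mismatches, both gap orientations, zero regions, score ties — but
they do not emulate the composition bias, repeats, homopolymers or
shared-ancestry structure of real genomic data.  Consequently the passing
suites demonstrate *algorithmic correctness* (agreement with the textbook
recurrence, exhaustive path enumeration at short lengths, and an
independent third-party aligner) rather than biological sensitivity of any
particular scoring scheme; choosing $\alpha, \beta, \gamma$ or a
substitution matrix appropriate to real data is the caller's decision.

Problem sizes used by the default verification runs: around 200 random
pairs at lengths 1–32 for the oracle and simulator-identity suites,
exhaustive enumeration at lengths up to 6, and one demonstration-scale
$128 \times 8192$ fill.  These sizes make the full suite complete within
tens of seconds while still covering every length-degenerate edge
(single-symbol sequences, all-zero matrices, maximum ties).

## Numerical and degenerate-input choices

* Scores, penalties and matrix entries are validated as integers; the gap
  penalty is stored as a non-negative magnitude and subtracted.
* A custom substitution matrix may be asymmetric; rows index the database
  symbol and columns the query symbol, and no symmetry is ever assumed.
* Sequences must be non-empty; ambiguity codes (e.g. `N` under DNA) are
  rejected at construction with the offending symbol and position named,
  rather than silently scored.
* `gap = 0` is legal (gaps become free); the tie rules above still make
  the traceback deterministic.
* The sequential aligner accepts any $M, N \ge 1$; only the array
  simulator imposes $M \ge N$.
* Packing pads the code vector to a whole byte; `unpack_directions()`
  restores the original length and shape exactly.

## Known limitations

* No affine gap model (separate opening/extension costs) — the direction
  alphabet would need more than four levels to disambiguate the assisted
  matrices' states.
* One optimal alignment is reported; co-optimal paths are resolved by the
  tie rules, not enumerated.
* `pe_count` is pinned to the query length: multi-pass operation of a
  smaller physical array over a longer query is not modeled.
* The cycle model is idealized (no pipeline fill/drain, memory port or
  clock-domain effects), so cycle counts are architectural, not timing,
  quantities.
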