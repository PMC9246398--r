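# swsystolic

Local pairwise sequence alignment (Smith-Waterman, linear gap penalty)
with a **stored direction matrix**: the forward dynamic-programming stage
records, for every cell, a two-bit code saying which recurrence term won,
and tracks the running maximum as it fills.  Traceback then reduces to
walking a chain of stored codes from the maximum-score cell to the first
zero — no score arithmetic, no re-derivation.  The package also contains a
**cycle-stepped simulator of a systolic processing-element array** (one PE
per query symbol, anti-diagonal wavefront, per-PE direction memories, a
chained maximum record) that is verified cell-for-cell against the
sequential aligner, plus GCUPS throughput accounting, FASTA I/O, a
synthetic sequence generator and a command-line tool.

It is aimed at people studying or prototyping hardware-style alignment
dataflows — the direction-memory/backtracking-chain organisation, its
cycle behaviour and its storage cost — while needing a bit-exact software
reference for the alignments themselves.

## The method

For a query $q = [q_1,\dots,q_N]$ and database sequence
$s = [s_1,\dots,s_M]$, with match/mismatch scores $\alpha,\beta$ (or a
full substitution matrix $P$) and linear gap penalty $\gamma \ge 0$:

$$H(i,j) = \max\{\,0,\ H(i-1,j-1) + P(s_i,q_j),\ H(i-1,j) - \gamma,\ H(i,j-1) - \gamma\,\}$$

with $H(i,0) = H(0,j) = 0$.  Alongside each $H(i,j)$ a direction code is
stored: **2** diagonal, **1** vertical (gap in the query row), **3**
horizontal (gap in the database row), **0** when the zero floor wins —
four levels, two bits per cell (`pack_directions()` gives the packed
form).  Ties go to the diagonal; a vertical/horizontal tie goes
horizontal.  Backtracking starts at the tracked maximum and follows codes
until it reads a 0.  CIGAR strings use query-relative SAM semantics
(2 → M, 3 → I, 1 → D).

The systolic simulator computes cell $(i, j+1)$ on PE $j$ at wavefront
step $t = i + j - 1$; an $M \times N$ fill takes exactly $M + N - 1$
cycles.  Peak throughput of an $N$-PE array at clock $f$ is
$N \cdot f \cdot 10^{-9}$ GCUPS (`gcups_from_frequency()`); achieved
throughput is cells divided by seconds (`gcups_from_time()`).

## Worked example

```r
library(swsystolic)
sc  <- scoring_scheme(match = 5, mismatch = -5, gap = 1)
res <- align("GATTACA", "GCATTAGA", sc)
print(res$alignment)
#> <sw_alignment> score 27, CIGAR 1M1D4M1D1I1M
#>   q  G-ATTA-CA
#>      | ||||  |
#>   s  GCATTAG-A
#>   region: rows 1..8, cols 1..7
```

Six matches (5 each) minus three single-symbol gaps (1 each) give the
score 27; the aligned region starts at row 1 of $s$ and column 1 of $q$
(all coordinates are 1-based matrix coordinates: rows index the database
sequence, columns the query).  The same inputs through the array
simulator:

```r
sim <- simulate_systolic("GATTACA", "GCATTAGA", sc)
print(sim)
#> <sw_sim> 7 PEs, 14 forward + 9 backtrack cycles
#> <sw_alignment> score 27, CIGAR 1M1D4M1D1I1M
#> ...
```

14 forward cycles is $M + N - 1 = 8 + 7 - 1$; `sim$forward` and
`sim$alignment` are identical to the sequential results.  Peak throughput
of a 128-PE array at 100 MHz:

```r
perf_report(128 * 8192, clock_hz = 100e6, pe_count = 128)
#> <sw_perf> 1,048,576 cells, 12.8000 GCUPS (peak)
```

From the shell (after `R CMD INSTALL`, the script is in the installed
package's `exec/` directory; it also runs in place from `exec/swalign`):

```sh
swalign align GATTACA GCATTAGA --format json
swalign simulate q.fasta s.fasta --swap --clock-mhz 100
swalign generate --n 128 --m 8192 --seed 7 --out pair.fasta
swalign selftest
```

`simulate --verbose` additionally emits the per-cycle trace on stderr as
tab-separated text with columns `step`, `pe`, `row`, `col`, `score`,
`direction` — one line per cell computation, in wavefront order.

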