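---
title: "Detecting coding regions by their period-3 spectral signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coding regions by their period-3 spectral signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(period3)
```

## The signal and the model

Protein-coding DNA is read in codons, and the unequal usage of the 64
codons leaves a statistical imprint: nucleotide occurrences repeat with a
period of three bases. In the frequency domain this shows up as excess
power at the normalized frequency $f = 1/3$ (one third of the sampling
frequency). Introns and intergenic background lack this enrichment, so a
sliding estimate of the $f=1/3$ power along a sequence rises over exons
and falls between them. This package implements that detector end to end.

The sequence is first mapped to numbers with the Voss encoding: four
aligned binary indicator vectors $u_A, u_C, u_G, u_T$, with
$u_X[i] = 1$ iff residue $i$ is $X$. At every unambiguous position
exactly one indicator is 1; at an `N` all four are 0, so ambiguous bases
contribute nothing to any power. Binary indicators also make the core
recursion exact integer arithmetic (below), which is why we store them as
integers rather than reals.

For one window $x[0..N-1]$ of one indicator, the single-bin power at
$f = 1/3$ is obtained with the Goertzel recursion

$$y[n] = x[n] + 2\cos(2\pi f)\,y[n-1] - y[n-2], \qquad y[-1]=y[-2]=0 .$$

At $f = 1/3$ the coefficient $2\cos(2\pi/3)$ is exactly $-1$, so the
recursion needs no multiplications at all:

$$y[n] = x[n] - y[n-1] - y[n-2],$$

and the squared magnitude of the bin is

$$P_X = y_N^2 + y_{N-1}^2 + y_N\,y_{N-1},$$

the general form $y_N^2 + y_{N-1}^2 - 2\cos(2\pi f)\,y_N y_{N-1}$
specialized to $f = 1/3$. This quadratic form is positive semidefinite
(it equals $\tfrac{1}{2}[(y_N+y_{N-1})^2 + y_N^2 + y_{N-1}^2]$), zero only
when both terms vanish. The four per-nucleotide powers are summed into the
window's combined power; the sum over an exact partition of positions is
what makes the combined statistic insensitive to which base carries the
periodicity.

Two numerical points are deliberate:

* `goertzel_recursion()` uses the coefficient $-1$ in exact form when
  `f_n == 1/3`, rather than evaluating `2*cos(2*pi/3)` (which rounds to
  $-1 + 4.4\times 10^{-16}$). The recursion has its poles on the unit
  circle, so a coefficient perturbation would otherwise grow linearly to
  quadratically with window length; using the exact value makes the
  general and specialized recursions bit-identical.
* On 0/1 input the specialized recursion is run in 64-bit integer
  arithmetic (`src/goertzel.cpp`), with $|y[n]| \le n$, so every window
  power is exact and bitwise reproducible — the property the
  serial/parallel equivalence contract relies on.

An independent oracle, `dft_power_period3()`, computes the same bin by
direct complex summation $|\sum_n x[n] e^{-2\pi i n/3}|^2$; the test suite
checks Goertzel against it on thousands of random windows. The `"fft"`
backend computes the full transform per window and extracts bin $k = N/3$;
it exists to mirror the FFT-based implementation strategy and agrees with
the Goertzel backend to floating-point tolerance. When the window length
is not divisible by 3 there is no exact $1/3$ bin: the oracle refuses, the
FFT backend takes the nearest integer bin with a warning.

## Sliding-window scan

`scan()` advances a `window`-bp frame by `step` bp and recomputes each
window from scratch; no incremental update is used, so the chunked and
parallel paths are trivially equivalent to the serial one and the
equivalence tests are meaningful. Parameters:

* `window` (default **351 bp**): the established compromise for exon
  detection — longer windows blur exon/intron boundaries, shorter ones
  are noisy. Must be $\ge 3$; lengths divisible by 3 give the exact bin.
* `step` (default **1 bp**): full-resolution scanning.
* `anchor` (default `"center"`): a window's value is reported at
  $i + (window-1)/2$ so track peaks align with exon midpoints (center
  anchoring requires an odd window). `"start"` reports plain window
  starts, which keeps bedGraph lines trivially interpretable.
* Power is reported raw — not normalized by $N$ or $N^2$ — matching how
  such tracks are conventionally plotted; any normalization is left to
  the caller.

The track has exactly $\lfloor (L - window)/step \rfloor + 1$ values.
`plan_chunks()` partitions window-start indices into runs of
`chunk_windows`; a chunk's residue span is $(m-1)\,step + window$ bp, so
adjacent spans share $window - step$ bp and each window is computed exactly
once. `scan_parallel()` executes chunks with `parallel::mclapply`, keyed
and reassembled by chunk index, and is bitwise identical to `scan()` for
the Goertzel backend regardless of `workers` and `chunk_windows`. The
default `chunk_windows = 50000` is a convenience granularity: large enough
that per-chunk overhead is negligible, small enough to balance load; the
result does not depend on it. `max_parallel_instances()` is a purely
advisory calculator for sizing concurrent instances on a device where each
instance runs four single-nucleotide transforms plus overhead against
processing-unit and memory budgets; it gates nothing.

## Region calling

The literature identifies coding regions from such tracks visually; to
make that reproducible, `call_regions()` uses an explicit rule that is a
repository choice, not an established standard:
threshold at $\tau = \text{mean} + k_\sigma \cdot \text{sd}$ (population
sd — dividing by $n$ — for determinism and because the track is the whole
population of windows, not a sample), take maximal runs of anchored
positions with power $\ge \tau$, merge runs separated by fewer than
`merge_gap` bp, and drop regions shorter than `min_len` bp. Defaults
($k_\sigma = 2$, `min_len = 30`, `merge_gap = 50`) are permissive: 30 bp
is shorter than essentially all real exons, and 50 bp bridges the dips a
351-bp window produces inside one exon. Region summaries (`peak_power`,
`mean_power`) are computed over the above-threshold positions so the
documented invariant peak $\ge$ mean $\ge \tau$ survives gap merging.
A constant track has $\tau$ equal to that constant, so the whole track
becomes one call — the degenerate case is defined, not an error.

Interval arithmetic is 0-based half-open everywhere (length =
`end - start`), matching BED and reproducing published exon lengths
directly. `merge_intervals()` unions overlapping *or touching* intervals;
applied to the packaged HFE2 exon fixture (five exons on chromosome 1,
with the 37-bp exon 3a nested inside the 560-bp exon 3b), it yields the
four distinct coding regions a detector should find.
`evaluate_calls()` scores calls against a truth set: a truth interval is
detected when a single call covers at least `min_overlap_frac` (default
0.5) of it; precision is the fraction of calls supporting some detection,
defined as 1 on an empty call set (logged).

## The synthetic generator

`generate_synthetic()` emulates the one feature the detector exploits and
nothing else: background positions are i.i.d. uniform over the four
bases; inside each truth region the sequence is drawn codon by codon,
with probability `bias` the dominant codon (default `ATG`) and otherwise
a codon uniform on all 64. `bias = 0` therefore reduces exactly to the
background distribution (uniform codons = uniform bases), `bias = 1`
gives a perfect 3-periodic repeat whose fully-overlapping 351-bp window
power is $3 \times 117^2$ by the impulse-train closed form, and
intermediate values interpolate the signal strength. Region lengths must
be divisible by 3 so the phase stays coherent within a region. All draws
are governed by one explicit seed and the caller's RNG state is restored.

What the generator does **not** emulate: GC/isochore structure, codon
correlations, splice signals, repeats, or realistic exon length
distributions. Passing the synthetic benchmark therefore demonstrates
that the pipeline recovers period-3-enriched regions of the stated
strength in uniform background — it does not certify detection rates on
real genomes, where enrichment is weaker and background is structured.
The benchmark conditions (20 kb, three 900-bp regions evenly spaced,
`bias = 0.8`, ten seeds, default scan and calling parameters) are fixed
as the package's reference study; at those conditions the pipeline
recovers essentially all regions with no false calls.

Problem sizes in the shipped tests were chosen to exercise every contract
at meaningful scale while staying quick: the serial/parallel equivalence
uses a 50-kb sequence over nine worker/chunk combinations, oracle
equivalence uses 1000 random windows up to 351 bp, and the benchmark runs
ten independent 20-kb simulations.

## Known limitations

* The calling rule is global-threshold based; long sequences with locally
  varying background favour a windowed or rank-based threshold instead.
* Power is phase-blind: reading frame and strand are not resolved, and
  overlapping exon variants merge into one called region by construction.
* Windows shorter than ~200 bp make the $f=1/3$ estimate noisy; windows
  not divisible by 3 only approximate the bin.
* `scan()` masks `base::scan` when the package is attached; use
  `period3::scan` or `utils::read.table`-family functions as needed.
* Real-genome validation (e.g. on the HFE2 locus itself) requires
  sequence data the package deliberately does not download; the packaged
  HFE2 fixture covers the interval arithmetic only.
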