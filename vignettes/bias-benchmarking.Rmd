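---
title: "Benchmarking small RNA library preparation bias with srnabias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking small RNA library preparation bias with srnabias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnabias)
```

## The benchmark

Small RNA sequencing converts miRNA abundance into read counts through a
chain of enzymatic steps — 3' adapter ligation, 5' adapter ligation or
circularization, reverse transcription, PCR — each of which prefers some
sequences over others. The dominant effect is sequence-dependent adapter
ligation, which can depress an individual miRNA's read share by orders of
magnitude. The community's standard yardstick for this bias is an
equimolar pool of synthetic miRNAs: since every member is present at the
same molar amount, every member should receive the same expected share of
reads, and any deviation is preparation bias.

For pool member $i$ with observed count $O_i$, expected fraction $f_i$
(equal to $1/n$ for an equimolar pool of $n$ members) and assigned depth
$D = \sum_i O_i$, the package computes

$$\mathrm{FD}_i = \log_2 \frac{O_i}{D\, f_i}$$

and classifies members as *accurate* when $|\mathrm{FD}_i| \le \tau$
(default $\tau = 1$, i.e. within ±2-fold; boundaries inclusive, since
"within two-fold" includes two-fold itself), *under* or *over* otherwise,
and *undetected* when $O_i = 0$. The percent of accurate members is the
statistic on which kits are compared, with a Welch two-sample t-test
across replicate libraries.

## The simulator and what it emulates

Real benchmark data requires sequencing runs, so the package ships a
generative model of library preparation whose ground truth is known
exactly. For each simulated "kit":

* **Ligation/capture bias.** Each reference sequence receives a relative
  capture efficiency $e_i = 2^{x_i}$, $x_i \sim N(0, \sigma)$, normalized
  so the best-captured sequence has $e = 1$. The log2-normal form is a
  modeling choice, not an empirical claim: published benchmarks report the
  *span* of bias (10^3–10^5-fold between extremes) but not its
  distributional shape, and a multiplicative spread with a single scale
  parameter is the simplest family that reproduces those spans. The
  default $\sigma = 3$ reproduces the ~2^16-fold ranges typical of
  two-adapter chemistries; $\sigma \approx 0.5$ emulates a low-bias
  single-adapter/circularization chemistry; $\sigma = 0$ is the exact
  unbiased control.
* **PCR bias.** Each sequence gets a per-cycle duplication probability
  $q_i = \mathrm{clamp}(q_\mathrm{base} + s\,(\mathrm{GC}_i - 0.5),\,
  0.05,\, 1)$ — PCR favors GC-rich templates — and contributes a
  deterministic weight $(1+q_i)^c$ after $c$ cycles (default
  $q_\mathrm{base} = 0.9$, slope $s = 0.2$, $c = 5$ cycles, matching
  low-cycle pool protocols; the model caps $c$ at 25 because the benchmark
  context keeps amplification below ~20 cycles).
* **Sampling.** Final read counts are one multinomial draw of the
  non-dimer depth with probabilities $\propto f_i\, e_i\, (1+q_i)^c$.
  Capture and amplification are deliberately collapsed into a single draw:
  treating the PCR weights as deterministic expectations (rather than
  resampling reads from realized pre-PCR molecule counts) keeps the
  per-reference counts exactly multinomial, so closed-form
  binomial/chi-square oracles apply and the unbiased control passes a
  goodness-of-fit test against uniformity. A branching-process PCR model
  would add variance without changing any statistic the benchmark reports.
* **Reads.** Each read is the reference sequence (U→T) plus the 3' adapter
  `TGGAATTCTCGGGTGCCAAGG`, truncated to the read length (36 nt by default,
  emulating short single-end runs; 50 nt also conventional). A fraction
  `dimer_rate` of reads (default 2%) are adapter-dimers: bare adapter with
  no insert. Qualities are a constant high-quality symbol because no stage
  of this analysis consumes them.

**What the simulator does not emulate:** sequencing errors and quality
decay, PhiX spike-ins, isomiR end-variation beyond what the counting
tolerance absorbs, cross-mapping between near-identical miRNA family
members (generated pool sequences are random and essentially orthogonal),
carrier effects of biological RNA backgrounds, and UMI structure. Passing
tests on simulated data therefore demonstrate that the *analysis* is
correct and calibrated, not that any particular wet-lab chemistry has a
particular bias; conclusions about real kits still require real equimolar
pool libraries.

## Read processing conventions

**Trimming.** `trim_adapter()` reproduces the semantics of the standard
small-RNA trimming invocation (`-a <adapter> -m 15`): the best occurrence
of the adapter — the full adapter anywhere in the read, or an adapter
prefix running off the 3' end — is found allowing mismatches and indels at
up to 10% of the aligned adapter length, preferring longer adapter matches
and then leftmost position; the occurrence and everything after it are
removed. Occurrences shorter than 3 nt are ignored (the trimming tool's
documented default minimum overlap); without this floor, every read whose
last base happens to equal the adapter's first base would lose it, and
trimming would not be idempotent. Kept reads shorter than 15 nt are
discarded and tallied. The implementation is an $O(nm)$ banded
dynamic program in C++; its contract is pinned by a test against a
brute-force oracle that enumerates every (start, length) pair with
`utils::adist`.

**Counting.** Mature-miRNA counting needs no gapped genome alignment, so
instead of wrapping an external aligner the package defines an exact,
testable matcher: a trimmed read is assigned to a reference when the two
agree over their shared prefix with at most `max_mismatches` substitutions
(default 0, maximum 2) and differ in length by at most 2 nt at the 3' end
(tolerating isomiR-like end variation). Among qualifying references, fewest
mismatches win, then smallest length difference; remaining ties share the
read fractionally ($1/k$ each), which is deterministic and
order-independent but means counts can be rational. Equivalence with any
specific external aligner's output is deliberately not promised.

**Subsampling.** Detection comparisons subsample *trimmed reads* (not
count tables) to a common depth — conventionally 200,000 — before counting
miRNAs with at least 5 reads (10 for deep-coverage detection curves).
Sampling is uniform without replacement, order-stable, and seeded.

## Cross-kit FN/FP attribution

When the same biological sample is profiled with two kits, per-miRNA
differential quantification is the log2 ratio of reads-per-million values
with a pseudocount of 0.5 raw reads (scaled into RPM units per library) to
keep undetected miRNAs finite and penalized. Discordances
($|\Delta| > \tau_d$, default 1) are attributed by comparing their
direction with each kit's synthetic-pool fold-deviation: if kit X reads a
miRNA lower and kit X under-captures it in the pool
($\mathrm{FD}^{pool}_X < -\tau_{pool}$), that is a false negative of kit X;
if instead the reference kit over-captures it, a false positive of the
reference kit; symmetrically for the other direction. The published
benchmark describes this analysis but never states the decision rule
explicitly, so the rule here is this package's formalization, recorded in
the output metadata. Two deliberate details: when *both* kits' pool biases
match the discordance direction the kit with the larger absolute pool bias
is charged (an exact tie is unattributed) — the symmetric tie-break is what
makes attribution exactly antisymmetric under swapping the kits — and pool
members undetected in the pool libraries enter with their floored
fold-deviation ($\log_2(0.5/E_i)$), which is strongly negative, i.e.
maximally under-captured.

## Numerical conventions and degenerate inputs

* Zero observed counts: class `undetected`; `log2_fd` floored at
  $\log_2(0.5/E_i)$ for plotting and attribution; counted as
  under-represented in the percentage summary (denominator = all pool
  members). The alternative `zero_policy = "omit"` drops them from the
  denominators.
* Percentages `under + accurate + over` sum to 100 exactly (one shared
  denominator).
* A library with zero assigned reads, a t-test between two constant
  groups, a standard curve with non-negative slope, and a subsample larger
  than its library are classed errors, never silent NaNs; Pearson columns
  with zero variance are flagged (`NA` + attribute) rather than propagated
  as NaN.
* qPCR quantification fits $C_q = a \log_{10}(\mathrm{conc}) + b$ by least
  squares on a dilution series of at least 3 points (the emulated
  validation panels span 8 logs, 200 pM–20 aM); efficiency is
  $10^{-1/a} - 1$, so perfect doubling gives $a = -\log_2 10 = -3.3219$
  and 100%. Base 10 matches the tenfold dilution convention.
* All randomness flows through a single seeded Mersenne-Twister scope per
  call; derived child seeds stay below $2^{31}$. Identical inputs and
  seeds give byte-identical FASTQ and report files.

## Replicate handling

Fold-deviation is computed per replicate library. The kit-level table used
for FN/FP attribution takes the per-miRNA *mean* of replicate log2
fold-deviations (then reclassifies); percent-accurate for the t-test is
per replicate, because the test compares replicate-level percentages.
Whether published density plots pool or average triplicates is not stated
anywhere authoritative; averaging is this package's convention, not a
claim about any published figure.

## The bundled benchmark design

`benchmark_config()` encodes the full study design: a 963-member equimolar
pool (19–24 nt, GC 0.2–0.8), two kits (σ = 0.5 "lowbias" vs σ = 3
"highbias", dimer rates 2% vs 10%), triplicate 2M-read pool libraries,
subsampling to 200,000 trimmed reads with a 5-read detection threshold, a
shared log2-normal biological abundance profile (σ = 3) sequenced at 1M
reads per kit for FN/FP attribution, and a tenfold dilution series
(10^6, 10^5, 10^4 reads) of the biological sample under the low-bias kit
for raw-count Pearson concordance. The dilution series uses the biological
sample rather than the equimolar pool because concordance across dilutions
is only informative when abundances span a wide range — correlating a
flat equimolar profile would measure only bias and shot noise. Replicate
counts, depths, thresholds and kit parameters are all configuration, not
constants. The test suite exercises the same stages at reduced sizes
(pools of 20–300, depths 10^3–10^4) to stay fast, and at the full 963 ×
2×10^6 scale in the end-to-end acceptance tests; the acceptance script
runs the full-scale design.

## Known limitations

* The log2-normal ligation model is a stand-in for an unknown true
  distribution; only its span is anchored to published observations.
* The counting matcher is exact by design and will not reproduce the
  idiosyncrasies of heuristic aligners on real, error-containing reads.
* Attribution quality degrades for miRNAs whose biological abundance is so
  low that both kits yield near-pseudocount RPMs; such members drift into
  `concordant`/`unattributed` regardless of planted bias.
* Raw-count Pearson correlation (the dilution-series convention) is
  dominated by the most abundant members; the `normalize = "rpm"` option
  exists but changes the question being asked.
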