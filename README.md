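# srnabias

Benchmarking ligation and amplification bias in small RNA sequencing
library preparation.

## The problem

Small RNA sequencing counts reads to quantify miRNAs, but the adapter
ligation steps of library preparation capture different miRNA sequences
with very different efficiencies — individual miRNAs can be
under-represented by as much as 10^4-fold relative to their true abundance.
The standard way to measure this bias is to sequence an **equimolar pool**
of *n* synthetic miRNAs: every member should receive the same share of
reads, so for member *i* with observed count *O_i* and expected count
*E_i = D / n* (at assigned depth *D*), the per-miRNA bias statistic is the
log2 fold-deviation

```
FD_i = log2(O_i / E_i)
```

A miRNA with |FD_i| ≤ 1 (within ±2-fold of expectation) counts as
**accurately quantified**; the fraction of accurate miRNAs is the
headline figure for comparing library preparation chemistries. Downstream
analyses build on the same counts: Welch t-tests on replicate
percent-accurate values, equal-depth subsampled detection (miRNAs with ≥ k
reads after subsampling every library to the same trimmed-read depth),
cross-kit differential quantification of a biological sample with false
negative / false positive attribution against each kit's pool accuracy,
dilution-series Pearson concordance, and qPCR standard-curve absolute
quantification (`Cq = slope·log10(conc) + intercept`, efficiency
`10^(-1/slope) - 1`).

`srnabias` implements this entire benchmark as a reusable pipeline, and —
because the real experiment needs sequencing runs — ships a
library-preparation **simulator** with known ground truth: per-sequence
ligation efficiencies drawn log2-normally (spread `sigma_log2`),
GC-dependent per-cycle PCR efficiencies applied as deterministic weights
`(1+q_i)^c`, adapter-dimer contamination, and exact FASTQ output. Every
stage of the analysis is therefore verifiable against planted truth.

It is aimed at people developing or evaluating small-RNA library
preparation protocols and at analysts who want a controlled testbed for
miRNA-seq quantification pipelines.

## Worked example

Simulate a heavily biased kit on a 963-member equimolar pool, then run the
read-level pipeline and the bias metrics:

```r
library(srnabias)

pool    <- build_equimolar_pool(963, seed = 42)          # 19-24 nt, 1/963 each
profile <- sample_bias_profile(pool, sigma_log2 = 3, seed = 1)
lib     <- simulate_library(pool, profile, depth = 2e6, seed = 7)

trimmed <- trim_adapter(lib$reads)   # cutadapt-style: -a TGGAATTCTCGGGTGCCAAGG -m 15
#> trim_result: 2000000 reads in; 2000000 with adapter, 0 without;
#>   40000 discarded (< min length); 1960000 kept

counts <- count_reads(trimmed$kept, pool)
fdt    <- fold_deviation(counts, pool, tau = 1)
#> fold_deviation_table 'library': 963 references, depth 1.96e+06, tau = 1
#>   under 78.5% | accurate 13.8% | over 7.7% (undetected 0.7%)
```

The 40,000 discarded reads are the simulated adapter-dimers (2% of the
library): after trimming they are empty and fall under the 15 nt minimum.
With `sigma_log2 = 3` the kit spans a ~2^18-fold capture range, so most
pool members are under-represented and only 13.8% land within ±2-fold of
the equimolar expectation — the signature of a strongly biased two-adapter
chemistry. A `sigma_log2 = 0.5` profile on the same pool yields ~93%
accurate. Comparing replicate percent-accurate values between two such
kits:

```r
tt <- compare_percent_unbiased(c(93.2, 93.0, 93.6), c(18.6, 19.1, 18.5))
#> t = 291.1, p = 8.8e-10   (Welch two-sample, two-sided)
```

`run_benchmark(benchmark_config(), "outdir")` executes the whole study
design — two preconfigured kits, triplicate 2M-read pool libraries, a
shared biological sample with FN/FP attribution, equal-depth detection at
200,000 reads, and a tenfold dilution series — writing TSV tables, SVG
figures and a machine-readable `summary.json`, byte-identically
reproducible for a fixed config. The same stages are available as shell
subcommands via `exec/srnabias` (`simulate`, `trim`, `count`, `subsample`,
`bias`, `compare`, `detect`, `correlate`, `run-all`).

## Documentation

The methods vignette (`vignettes/bias-benchmarking.Rmd`) describes the
simulator's model and its assumptions, every tunable parameter with its
default and rationale, the numerical conventions (zero-count handling,
boundary inclusivity, tie-breaking), and known limitations. Function-level
documentation lives in the roxygen comments in `R/`.
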