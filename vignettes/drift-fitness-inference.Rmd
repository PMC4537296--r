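---
title: "Inferring per-mutation fitness effects from laboratory neutral drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring per-mutation fitness effects from laboratory neutral drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftDFE)
```

## The experimental design this package models

A gene is subjected to iterative rounds of *neutral drift*: error-prone
amplification introduces on average $\lambda$ nucleotide substitutions per
gene copy per round, and a functional selection then purges copies whose
protein no longer works. The naive pool after one round of mutagenesis and
before any selection (G0) and the surviving pools after $n$ rounds (G$n$)
are deep-sequenced with short reads. Because selection acts every round
while mutagenesis keeps re-introducing every mutation, the frequency
trajectory of each mutation encodes its average fitness effect across the
many genetic backgrounds in which it occurred.

## The inference model

Let $f(G_0)$ be a mutation's per-round occurrence frequency and $W$ its
per-round relative fitness (the factor by which selection multiplies its
frequency). Each round the observed frequency is the inherited frequency
plus the fresh input, times $W$:

$$f(G_n) = \left[f(G_{n-1}) + f(G_0)\right]\cdot W
\quad\Longrightarrow\quad
\frac{f(G_n)}{f(G_0)} = \sum_{k=1}^{n} W^k .$$

The ratio is strictly increasing in $W$, equals $n$ at neutrality and 0
for lethal mutations, but has no closed-form inverse for general $n$.
`invert_ratio()` therefore evaluates the forward sum on a grid of $W$
values from 0 to `w_max` (default 3.5) in steps of `grid_step` (default
0.01) and interpolates linearly between adjacent grid ratios; ratios above
the ratio attainable at `w_max` are capped and flagged rather than
extrapolated, and a ratio of exactly 0 maps to $W = 0$. The forward and
inverse maps agree to within one grid step over the whole scale and all
round counts used in practice (this identity is asserted in the test
suite).

Assumptions worth keeping in mind:

* **One multiplicative selection step per round.** Bench protocols often
  apply several enrichment cycles per round; the simulator exposes
  `enrichment_cycles` to probe this, but the estimator always interprets
  $n$ as the number of multiplicative steps. If each round in fact
  multiplies frequencies $E$ times, fitted $W$ values are effectively
  $W^E$ on the per-cycle scale.
* **Epistasis is averaged over.** Short reads do not reveal which
  mutations co-occur on a gene copy, so $W$ is a background-averaged
  effect; hitchhiking and clonal interference are mitigated by the
  re-introduction of every mutation each round, not eliminated.
* **Frequencies are small.** The geometric model treats per-mutation
  frequencies as multiplying freely; once a mutation's carrier frequency
  becomes a substantial fraction of the pool, growth saturates and fitted
  $W$ for strongly beneficial mutations is biased downward.

## From reads to frequencies

`map_reads()` places each read at its best ungapped offset on the
concatenated upstream + ORF reference (fewest mismatches, ties to the
smallest offset), keeping placements with at most `max_mismatches`
(default 6) and discarding reads shorter than `min_run` (default 24 nt);
indels are out of scope. `count_codon_mutations()` tallies, per codon
position, the reads whose *intact* codon — all three bases inside the read
and outside the `edge_trim` bases at each read end — differs from the
reference. A codon overlapping the trimmed edge contributes neither to the
mutation count nor to coverage, which keeps frequencies unbiased. The edge
width is not standardized across sequencing chemistries; 2 nt per end is
the default and is logged with every run.

The sequencing-error floor is estimated from an upstream region that never
went through mutagenesis: the mean per-position mutation frequency over
those codons (`estimate_background()`). `net_frequencies()` subtracts this
single per-library scalar from every codon-variant frequency, clamping at
zero and flagging below-background variants; the per-position background
values are retained only as a diagnostic. Frequencies of all codon
variants yielding the same amino-acid change are then summed
(`aggregate_frequencies()`).

Two consequences of subtracting a *per-position* background from
*per-variant* frequencies deserve mention. First, since a position's error
mass is spread over nine single-nucleotide variants, the subtraction is
conservative — it over-corrects each individual variant. At realistic
error floors this depresses naive-pool frequencies by a few percent more
than selected-pool frequencies, giving a small upward bias in fitted $W$
that is strongest for the rarest (transversion) variants and for small
$n$. Second, the same asymmetry inflates the transition/transversion ratio
recovered from net frequencies slightly above the spectrum that generated
the data. Both effects are visible in the simulation-based checks and stay
well inside the acceptance tolerances; analyses that need an unbiased
spectrum can compute it from raw rather than net frequencies.

For the minority of mutations whose naive-pool frequency falls below the
background, the occurrence rate cannot be read off G0 directly; following
standard practice the rate is taken from the naive pool's nucleotide
substitution table instead (`expected_g0_frequency()`), summed over the
codon routes to the amino-acid change. Mutations with neither an observed
nor a substitutable rate are flagged `undefined` and excluded from DFE
denominators; they are counted in the fit's QC block.

## Thresholds and classification

Synonymous and nonsense mutations act as internal calibrators: synonymous
changes should be (nearly) neutral and nonsense changes unambiguously
deleterious. `derive_thresholds()` sets

* deleterious boundary: synonymous mean $-\,2$SD (per library, averaged
  across libraries) — a deliberately conservative choice that
  under-calls rather than over-calls deleterious effects;
* nearly-neutral boundary: synonymous mean $-\,1$SD;
* beneficial boundary: synonymous mean $+\,2$SD;
* highly-deleterious boundary: nonsense mean $+\,2$SD.

`classify_wrel()` applies the half-open partition
$(\le h]$, $(h, d]$, $(d, nn]$, $(nn, b]$, $(> b)$. With degenerate
(zero-variance) calibrator sets the boundaries may collapse; the
constructor allows equal boundaries so that such edge cases classify
rather than fail. For reporting, `round_thresholds()` rounds to one
decimal (the convention under which an averaged 0.62 is applied as 0.6);
raw values are always retained. The fixed set
$\{0.3, 0.6, 0.8, 1.1\}$ is available as `thresholds = "paper_default"`
for comparability across datasets.

## Summaries

`dfe_histogram()` bins fitness values in 0.1-wide half-open bins up to an
open top bin (default $>1.4$); eliminated mutations ($W = 0$) sit in the
first bin and are also tallied separately. `frequency_weighted_dfe()`
reports the share of the selected pool's total mutation frequency per
fitness range, and `fold_change()` the log ratio of shares between rounds
(base 10 by default; the base is a free choice and configurable).
`mutational_loads()` returns the per-gene nucleotide load $N_t$, the
nonsynonymous and synonymous amino-acid loads $N_a$, $N_s$ and their
ratio. `positional_wrel()` scores each position as
$\sum_i W_i\,\log_2(1 + 10 f_i)$ over the single-nucleotide mutations at
the position; because this frequency-weighted sum is sometimes more useful
as a weighted *average*, the normalized variant (divided by
$\sum_i \log_2(1+10f_i)$) is also provided, and compensatory-mutation
calls (`call_compensatory()`) accept either: a mutation is called when its
own $W$, or its position's normalized score, exceeds the beneficial
boundary.

## Predictor and constraint comparisons

External scores (PROVEAN/SIFT-like predictors, FoldX-style stability
changes, distances to the reaction center, local closeness, per-position
evolutionary rates, ortholog-divergence annotations) are consumed from a
documented TSV schema and never computed here. `confusion_vs_predictor()`
benchmarks a score against the drift truth (deleterious at $W \le 0.6$),
optionally excluding the borderline nearly-neutral band;
`score_wrel_correlation()` reports both rank and linear coefficients since
the appropriate one depends on the score's scale. Distribution overlap is
tested with a two-sample Kolmogorov–Smirnov statistic computed directly
from the empirical CDFs with the classical asymptotic p-value
(`ks_two_sample()`), so results do not depend on any statistical package's
version-specific exact-p switching; the test suite cross-checks it against
both a brute-force max-gap oracle and `stats::ks.test`.

## The forward simulator

`simulate_drift()` emulates the bench protocol: per round, each of
`population` gene copies gains Poisson(`lambda`) substitutions at uniform
ORF sites with alternative bases drawn from a substitution matrix
(default tuned to a transition/transversion ratio of 1.3, typical of
error-prone PCR and comparable to enterobacterial divergence spectra);
the next generation is drawn by weighted multinomial resampling with gene
weight $\prod_i w_i$ — soft selection at constant population size, which
matches the definition of $W$ as a per-round frequency multiplier.
Defaults are the drift conditions the package is designed around:
$\lambda = 2.2$ mutations/gene/round, 40-nt reads, and a population of
$2\times10^4$ copies as a frequency-space stand-in for the $\ge 10^5$
transformants of a bench round.

True fitness maps come from `make_fitness_map()`: nonsense mutations
lethal, synonymous neutral, and missense drawn from a configurable mixture
whose default — one third lethal, about a third more deleterious, a
nearly-neutral band, a neutral mass and a 3% beneficial tail — reproduces
the continuum shape of experimentally inferred DFEs in which roughly two
thirds of missense mutations are deleterious.

`sequence_population()` offers two readouts: a fast direct-count mode
(binomial counts at a stated depth, plus error-only counts over the
upstream region at a uniform per-base error `error_rate`) and a read mode
that emits fixed-length reads from random gene copies with injected base
errors. The default error floor of $10^{-4}$ per base reflects an
effective post-filtering short-read error rate: published drift datasets
show background thresholds well below per-variant naive frequencies, which
is only consistent with a sub-$10^{-3}$ effective floor.

Deliberate simplifications, and what they imply for validation: gene
copies are sets of mutation events relative to the reference (a second hit
at an already-mutated site is drawn against the reference base and kept as
a separate event — negligible at realistic rates but formally a
frequency-space approximation); fitness is multiplicative with no
epistasis, so simulation-based recovery checks validate the estimator's
arithmetic, sampling behavior and background handling, *not* its
robustness to epistatic interactions, mutation-rate heterogeneity along
the gene, or bottlenecks — none of which the simulator generates.

## Problem sizes and numerical checks

The packaged validation uses: parameter recovery on a 60-codon gene, 10
rounds, $\lambda = 2.2$, population $2\times10^4$, sequencing depth
$10^5$ per position, with true effects on the discrete grid
$\{0, 0.2, \ldots, 1.2\}$ (Spearman agreement between true and fitted
effects, and the mean fitted value of true-neutral mutations, are the
acceptance statistics); neutral-accumulation checks on a 30-codon gene
over 5 rounds against the $n\lambda$ expectation with a standard error
that includes the resampling-genealogy variance
$\lambda\,n(n+1)/2/N$; and a study-scale drift (329 codons, 3 rounds)
through the complete pipeline. All generators are seeded; reruns are
bit-identical.

## Known limitations

* Analyses of the original methyltransferase drift dataset require its
  processed supplementary tables, which are not redistributable with the
  package; the corresponding dataset-scale checks run only when those
  tables are supplied locally.
* Double- and triple-nucleotide codon variants are enumerated and counted
  but excluded from fitness inference; insertions, deletions and
  translational slippage are out of scope.
* The mapper is exhaustive and substitution-only — appropriate for short
  reads on a single small reference, not a general-purpose aligner.
* Capped fitness values (`w_max`) are lower bounds, not estimates, for
  extremely enriched mutations.
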