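# driftDFE

Infers the **relative fitness effect** of every single-nucleotide mutation
in a gene from deep sequencing of gene ensembles subjected to a *laboratory
neutral drift*: iterative rounds of random mutagenesis followed by
purifying selection for the protein's own function. The result is a
distribution of fitness effects (DFE) over the gene's complete
single-nucleotide mutational space, obtained under conditions that mimic
the gradual accumulation of mutations in natural protein evolution rather
than the one-shot tolerance measured by most deep mutational scans.

## Who this is for

Groups running mutagenesis–selection drift experiments (or re-analyzing
published ones) who need a tested, reproducible path from raw short reads
or codon count tables to per-mutation fitness values, category calls,
DFE/load summaries, and benchmark comparisons against variant-effect
predictors — plus a forward simulator to validate the whole pipeline
without any external data.

## The model

Let `f(G0)` be a mutation's frequency in the naive (mutagenized,
unselected) pool — its per-round rate of occurrence — and `f(Gn)` its
frequency after `n` rounds of mutagenesis plus selection. Each round, the
surviving frequency is the inherited frequency plus the newly arising one,
multiplied by the mutation's per-round relative fitness `w`:

```
f(Gn) = [f(Gn-1) + f(G0)] · w      =>      f(Gn) / f(G0) = Σ_{k=1..n} w^k
```

`w = 1` (neutral) gives `f(Gn) = n·f(G0)`; `w = 0` gives 0 (eliminated);
`w > 1` marks enrichment, typically by compensatory, stabilizing
mutations. The sum has no closed-form inverse for general `n`, so `w` is
recovered on a fitness grid (0 to 3.5, step 0.01) with linear
interpolation. Frequencies are background-corrected: the sequencing-error
floor is estimated from an unmutagenized region upstream of the ORF and
subtracted; naive-pool frequencies below that floor are replaced by rates
from the pool's nucleotide substitution spectrum. Category thresholds are
calibrated from internal controls — synonymous mutations (mean − 2SD sets
the deleterious boundary, mean + 2SD the beneficial one) and nonsense
mutations (mean + 2SD sets the highly-deleterious boundary) — yielding the
five-way classification highly-deleterious / deleterious / nearly-neutral /
neutral / beneficial.

## Worked example

Simulate a 60-codon gene drifting for three rounds under the default
fitness-effect mixture, sequence the naive and selected pools, and fit:

```r
library(driftDFE)

g     <- random_gene(60, upstream_L = 20, seed = 101)
truth <- make_fitness_map(g, seed = 102)
sim   <- simulate_drift(g, truth, rounds = 3, lambda = 2.2,
                        population = 2e4, seed = 103)
g0 <- sequence_population(sim, 0, depth = 1e5, seed = 104)
g3 <- sequence_population(sim, 3, depth = 1e5, seed = 105)
f0 <- net_frequencies(g0, estimate_background(g0, g), g)
f3 <- net_frequencies(g3, estimate_background(g3, g), g)

fit <- drift_fit(f0, f3, n = 3, gene = g, thresholds = "paper_default")
summary(fit)
```

```
Fitness-effect summary for 'G3' (round 3)
  missense    n =  350  mean wrel = 0.391  SD = 0.433
  nonsense    n =   15  mean wrel = 0.000  SD = 0.000
  synonymous  n =   59  mean wrel = 1.012  SD = 0.065
Category composition:
            category
class        beneficial deleterious highly_deleterious nearly_neutral neutral
  missense           20          54                186             45      45
  nonsense            0           0                 15              0       0
  synonymous          6           0                  0              0      53
Wrel thresholds: highly-deleterious <= 0.3 < deleterious <= 0.6 < nearly-neutral <= 0.8 < neutral <= 1.1 < beneficial
```

Synonymous mutations sit at neutrality (mean 1.01), nonsense mutations are
fully purged, and most missense mutations fall at or below the deleterious
boundary — the DFE shape the drift design is meant to expose.
`coef(fit)` returns the named wrel vector, `plot(fit)` the binned DFE,
`predict(fit)` the model-implied selected-pool frequencies, and

```r
mutational_loads(f3, fit)
#> Loads for 'G3' (round 3): Nt = 3.323, Na = 1.522, Ns = 1.801, Na/Ns = 0.85
```

gives the per-gene mutational loads. `run_pipeline()` drives the same
stages (including read mapping from FASTQ/SAM, per-library background
estimation, predictor benchmarking via `confusion_vs_predictor()` and
constraint comparisons via `constraint_distributions()`) from a library
manifest and writes deterministic TSV outputs.

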