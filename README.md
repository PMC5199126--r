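# batchevol

Modelling adaptation under serial-batch propagation — the regime of most
microbial evolution experiments, where populations repeatedly cycle through
a bottleneck of *N* cells, a lag phase, exponential growth to *2^M N* cells,
and random subsampling back to *N*. The package was built around budding
yeast adapting to arsenite stress, where single mutations (loss of the
aquaglyceroporin gene *FPS1* or its activator *ASK10*, duplication of the
exporter *ACR3*) improve two fitness components at once — the lag time λ and
the doubling time τ — and that positive pleiotropy drives fixation at
extraordinary speed. It is aimed at experimental-evolution and population
genetics researchers who want to turn measured lag/doubling-time phenotypes
into selection coefficients, fixation times, drift-loss probabilities and
mutation-rate bounds.

## What it computes

**Deterministic competition.** Within a cycle each genotype grows as
N<sub>i</sub>(t) = N<sub>i</sub>(0)·2^((t−λ<sub>i</sub>)/τ<sub>i</sub>)
after its lag; the cycle ends when the total reaches 2^M N. The
per-generation selection coefficient is the regression slope of ln(r),
r = N<sub>mut</sub>/N<sub>wt</sub>, on cumulative generations at cycle ends,
with the closed form (resident setting the cycle end)

> s = ln 2 · ( τ₁/τ₂ − 1 + (λ₁ − λ₂)/(M·τ₂) )

splitting exactly into a doubling-time and a lag term.

**Individual-based simulation.** A genotype-structured stochastic engine
(synchronous divisions, per-division mutation, exact multivariate
hypergeometric bottlenecks; C++ core) runs three campaigns: competition
assays from a single mutant cell, targeted-locus evolution of the
FPS1/ASK10/ACR3 channels across mutation-rate multipliers, and a
750-set factorial sweep over mutation parameters under three
genotype–phenotype maps (doubling-only M1, positively pleiotropic M2,
random-pleiotropy M3) with a gamma distribution of fitness effects and
diminishing-returns epistasis.

**Growth-curve phenomics and estimators.** Extraction of lag, doubling time
and growth efficiency from plate-reader curves with founder normalization;
the fluctuation-assay p0 mutation-rate estimator; the Poisson
standing-variant probability; and the variant-trajectory confidence filter.
Synthetic-data generators make the whole pipeline testable offline.

## Worked example

Compete the reconstructed *FPS1* genotype (λ = 276.6 min, τ = 130.2 min)
against the stressed wild type (804.8, 162.3), starting from one mutant cell
in a bottleneck of 10^5:

```r
library(batchevol)
p   <- batch_protocol(bottleneck = 1e5, doublings_per_cycle = 5, n_cycles = 20)
wt  <- growth_law(lag = 804.8, doubling_time = 162.3, initial_count = 1e5 - 1)
mut <- growth_law(lag = 276.6, doubling_time = 130.2, initial_count = 1)
fit <- compete_deterministic(wt, mut, p)
summary(fit)
#> s (regressed)          : 0.6539
#> s (analytic)           : 0.7333 = 0.1709 (doubling) + 0.5624 (lag)
#> fixation (>= 99%) at   : generation 25
#> cycles in trajectory   : 7
```

The regressed coefficient (0.65 per generation) is the slope actually
realized over the whole trajectory — the analytic 0.73 holds only while the
wild type still dominates the cycle end. The mutant passes 99% frequency at
generation 25, i.e. five transfer cycles. The trajectory itself
(`as.data.frame(fit)`) shows why: the frequency goes 1e-5 → 4e-4 → 0.015 →
0.35 per cycle. Under drift the same genotype is essentially never lost:

```r
res <- run_competition_ibm(genotype_phenotype(804.8, 162.3),
                           genotype_phenotype(276.6, 130.2),
                           p, n_replicates = 25, seed = 1)
res
#> IBM competition: 25 replicates, 20 cycles; mutant lost in 0 (0%)
```

whereas a variant carrying only the doubling-time benefit (λ = 804.8,
τ = 130.2) is lost by drift in a substantial fraction of replicates.

A command-line wrapper over the same functions is installed at
`inst/cli/batchevol.R` (subcommands `compete-det`, `compete-ibm`, `evolve`,
`sweep`, `phenomics`, `simulate-data`, `estimate`; YAML config, JSON
manifest with the recorded seed).

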