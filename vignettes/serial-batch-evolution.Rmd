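---
title: "Modelling serial-batch experimental evolution with batchevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serial-batch experimental evolution with batchevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchevol)
```

## The system being modelled

`batchevol` models microbial populations propagated in a serial-batch
regime: a bottleneck of $N$ cells is inoculated into fresh medium, grows
through a lag phase and then exponentially until the population has doubled
$M$ times, and $N$ cells are randomly subsampled to found the next cycle.
The motivating system is budding yeast adapting to arsenite stress, where
fitness decomposes into two genetically determined components per genotype
$i$ — the lag time $\lambda_i$ (minutes until the first cell division within
a cycle) and the doubling time $\tau_i$ — plus a third component, growth
efficiency (total yield), that is measured from growth curves but excluded
from the evolutionary models because its fitness contribution in this regime
is doubtful.

Within a cycle a genotype grows deterministically as

$$N_i(t) = N_i(0)\, 2^{(t-\lambda_i)/\tau_i} \quad (t > \lambda_i),$$

with no net growth before $\lambda_i$; the cycle ends at the time $t_{end}$
at which the total population reaches $2^M N$. The package's default
conditions are the study's: $N = 10^5$, $M = 5$, with stressed wild-type
phenotype $(\lambda, \tau) = (805, 162)$ min and unstressed wild-type
phenotype $(271, 126)$ min.

## The deterministic competition model

`compete_deterministic()` competes a resident against a mutant over repeated
cycles, solving $t_{end}$ each cycle by Brent root finding on the monotone
total-size function (relative tolerance $10^{-10}$; the bracket starts at 0
rather than at the longest lag, because once the mutant dominates, the cycle
can end before the slower genotype's lag is over). Both subpopulations are
then diluted proportionally back to $N$ and lags restart.

The per-generation selection coefficient is the OLS slope of
$\ln r$, $r = N_{mut}/N_{wt}$, at cycle ends (including the $t = 0$ point)
against cumulative generations counted as $M$ per cycle. The closed-form
counterpart, assuming the resident sets $t_{end}$, is

$$s = \ln 2\left(\frac{\tau_1}{\tau_2} - 1 +
  \frac{\lambda_1 - \lambda_2}{M\tau_2}\right),$$

an exactly additive decomposition into a doubling-time term and a lag term
(`analytic_selection_coefficient()`); the lag benefit dilutes as $M$ or the
mutant doubling time grows.

**Whole-cell dilution.** By default each transfer rounds every
subpopulation to an integer number of cells (`dilution = "whole-cells"`):
bottlenecks move discrete cells, and a lineage whose expected transfer falls
below half a cell is gone. After the mutant fixes, the wild-type lineage
therefore goes extinct within a few cycles and the ratio trajectory — and
hence the regression window — ends there. This matters quantitatively: the
regressed coefficient mixes the steep early phase (resident sets $t_{end}$)
with a shallower late phase (mutant sets $t_{end}$), so letting an
infinitesimal wild-type tail persist forever (`dilution = "continuous"`)
drags the slope down. For the three reconstructed arsenite-resistance
genotypes the whole-cell convention gives $s = 0.654$ (FPS1, lag 276.6 /
doubling 130.2), $0.414$ (ASK10, 503.3/134.6) and $0.356$ (ACR3,
630.4/122.8), versus $0.600/0.389/0.338$ under continuous dilution. The
pleiotropic FPS1 genotype, started from a single cell, first exceeds 99%
frequency at cycle-end generation 25.

## The individual-based model

`run_competition_ibm()` and `run_evolution()` simulate the same regime with
discrete cells and genetic drift. The state is genotype-structured (lineage
counts, not individual cell records), because all cells created together
with the same genotype divide synchronously. The event rules are:

* a lineage's first division in a cycle happens at $\lambda + \tau$ after
  the cycle start and every $\tau$ thereafter, consistent with the
  deterministic growth law above (at $t = \lambda$ the population still has
  its inoculum size; the first completed doubling is one $\tau$ later);
* each division doubles the lineage; after each division event the mutation
  model converts a binomially sampled number of the $n$ just-divided
  daughters into new single-cell lineages (at most one mutation per daughter
  per event — multiple hits are negligible at these rates);
* a lineage born mid-cycle divides one own doubling time after birth; lag
  applies only at cycle starts;
* the cycle stops at the first division event at which the total reaches
  $2^M N$ (synchronous doublings make the total lumpy, so the equality the
  protocol prescribes cannot be hit exactly); simultaneous events are
  processed in lineage order with the stop check after each doubling, for
  reproducibility;
* exactly $N$ cells are then drawn without replacement (multivariate
  hypergeometric across lineages, built from sequential conditional
  univariate draws of `rhyper`), empty lineages are pruned, and the next
  cycle starts.

There is no cell death, no ploidy change and no cell–cell interaction.
The within-cycle event loop is implemented in C++ (all randomness through
R's RNG, so runs are reproducible from `set.seed()`); a pure-R reference
engine with a user-supplied mutation-hook contract (`advance_cycle()`)
implements the identical rules and is used to cross-check the compiled
engine — bit-identically for mutation-free runs, statistically under
mutation. A 50-cycle run at $N = 10^5$, $M = 5$ with basal mutation rates
takes well under a second.

**Quantization.** Synchronous integer divisions mean a mutant completes a
whole number of divisions per cycle where the continuum model grants a
fractional exponent. The stochastic mean trajectory therefore cannot match
the deterministic continuum model pointwise; the package's tests check
agreement in fixation timing (within one cycle) and monotonicity instead.
The same quantization caps the doubling-time-only FPS1 mutant at 6 divisions
per cycle (64 cells against the wild type's 32-fold growth), which yields a
drift-loss probability of about 0.21 from a single founding cell — the
qualitative contrast with the pleiotropic variant (1024 cells per cycle,
essentially never lost) is stark, but smaller than the published loss count
for the doubling-time-only scenario, whose generating mechanism we could not
reconstruct from the stated rules (see README, reproducing the results).

## Genotype–phenotype maps

`dfe_mutation_model()` implements the random fitness-effect map. Per
daughter cell, a mutation arises with probability $G\mu$ ($G$ the genome
size, default $1.2\times 10^7$ bp — the map needs an overall per-division
rate and the study quotes only the per-bp rate $\mu = 0.33\times 10^{-9}$,
so $G$ is configurable); it affects fitness with probability $y$ (default
0.034) and is then beneficial with probability $z$ (default 0.13). Three
pleiotropy variants: M1 affects doubling time only; M2 affects doubling time
and lag with the same sampled coefficient and direction (positive
pleiotropy); M3 samples each component's magnitude and direction
independently.

**Effect sizes and the $\beta$ bridge.** Non-neutral effect magnitudes come
from a gamma distribution with shape $\alpha = 2$ and scale $\beta$ quoted
in minutes (empirical value 33; the sweep grid uses 13.3–47). Because the
conversion formulas consume a dimensionless raw coefficient $s_r$, the
package samples a raw doubling-time change $\Delta T_{raw} \sim
\Gamma(\alpha, \beta)$ and inverts the saturating conversion

$$\Delta T_{wt} = T_{wt}\frac{s_r}{s_r + 1}, \qquad
  s_r = \frac{\Delta T_{raw}}{T_{wt} - \Delta T_{raw}},$$

so that $\beta$ keeps its printed units; draws at or beyond $T_{wt}$ map to
$s_r = \infty$ and are absorbed by the truncation of $\Delta T_{wt}$ at
$T_{wt} - T_{wt,N} = 36$ min. This bridge is the single largest interpretive
choice in the package and is isolated behind `effect_on_doubling()` /
`effect_on_lag()` so the alternative (a dimensionless rescaling of $\beta$)
is switchable. The lag change uses the rearranged lag-selection identity
$\Delta\lambda = s_r M \tau$ (the $\ln 2$ factors of the per-generation
scale cancel), truncated at $L_{wt} - L_{wt,N} = 534$ min.

Beneficial effects shrink with diminishing-returns epistasis,

$$\Delta T_G = \frac{T_G - T_{wt,N}}{T_{wt} - T_{wt,N}}\,\Delta T_{wt},$$

applied component-wise (the lag analogue uses the lag bounds; the study
states the rule for doubling time and simulates lag under the same
asymptotic-approach behaviour, so we extend it by analogy). Deleterious
effects are sampled from the same gamma, applied with opposite sign and
capped at the stressed wild-type values: the founder is already the worst
phenotype the stress admits, so super-sick genotypes are not modelled — they
would be purged by selection regardless, and the cap keeps the state space
bounded. Together the caps guarantee every phenotype stays inside
$[126, 162]$ min doubling and $[271, 805]$ min lag, so population-mean
recovery can never exceed 100%.

**Targeted loci.** `targeted_mutation_model()` replaces the random map with
three empirical channels: loss-of-function SNPs in *FPS1* and *ASK10*
(per-division probability = target size $\times$ per-bp rate) and
duplication of *ACR3* (basal rate $3\times 10^{-7}$ per division). Allele
effects are the reconstructed genotypes' measured phenotypes. Under complete
negative epistasis a genotype's phenotype is its single fittest allele's
phenotype — fittest by analytic selection coefficient against the founder,
which weighs both components; ranking by doubling time alone would make
ACR3 (122.8 min doubling but 630.4 min lag) outrank FPS1 and, worse, let an
ACR3-fixed population absorb FPS1 mutations with no phenotypic effect. SNP
target sizes are user configuration, since deriving them requires an
external variant-effect database; the defaults (FPS1 200 bp, ASK10 150 bp)
come from gene-length and loss-of-function site-density reasoning: roughly
5% of the ~6000 possible single-base changes in the ~2 kb *FPS1* coding
sequence create premature stops, plus conserved-site missense changes, give
an effective target of a few hundred base-pair equivalents; *ASK10* gets a
somewhat smaller target as only part of its sequence regulates the relevant
channel. These were fixed once, before any simulation, and are deliberately
conservative.

## The three campaigns

* **Competition assays** (`run_competition_ibm()`): 20 cycles from a single
  mutant cell, mutation disabled; reports per-cycle frequencies and loss
  flags.
* **Targeted-locus rate scan** (`run_rate_scan()`): 25 replicates $\times$
  50 cycles at 1/3/5/10$\times$ the basal rates; per replicate the
  founder-extinction generation ($(cycle)\times M$ at the first
  post-bottleneck state without founder cells), the number of allele classes
  above 5% at the end, and the dominant class (largest summed frequency at
  the final cycle; each lineage is attributed to the allele class that
  determines its phenotype, so class frequencies partition the population).
  At basal-to-3$\times$ rates several allele classes win across replicates
  while extinction times tighten; at 5–10$\times$ the FPS1 class fixes
  almost always, erasing heterogeneity — the pattern that brackets the
  plausible mutation rate between 1$\times$ and 3$\times$.
* **Pleiotropy sweep** (`run_sweep()`): one population per mutation
  parameter set per map variant, paired seeds across variants. The full
  factorial grid (`parameter_grid()`) crosses $\{1/5, 1/3, 1, 3, 5\}$
  multiples of $\mu$, $y$ and $z$ with six $\beta$ values — 750 sets; the
  study quotes 500 without listing the dropped combinations, so the package
  generates the full factorial and supports subsetting. Summaries are the
  generations to 25/50/75% recovery of the doubling-time gap and a "fast
  scenario" flag (75% within 100 generations). Because the grid cardinality
  and the $\beta$ bridge are interpretive, sweep-level outputs are treated
  as property-level results (M2 adapts faster than M1 under matched seeds),
  not as exactly reproducible counts.

Recovery is expressed as $100(T_{stressed} - T)/(T_{stressed} -
T_{unstressed})$ percent, recorded at every cycle end (every 5 generations).
`generations_to_recovery()` first fits a monotone non-decreasing curve by
least squares (`stats::isoreg`) and reports the first recorded generation at
which the fitted curve meets each threshold; we deliberately do not
interpolate between samples by default — a step from 0 to 100% between
generations 5 and 10 is evidence the threshold was crossed by generation 10,
not at an interpolated 6.25 — but `interpolate = TRUE` is available.

## Growth-curve phenomics

`preprocess_curve()` applies light running-median smoothing (window 5
readings), subtracts the background (mean of the first three smoothed
readings) with a floor at $10^{-3}$ OD, and applies an optional monotone
OD-to-population-size calibration (identity by default; the empirical
calibration of the original plate-reader pipeline is instrument-specific
and therefore a hook).

`extract_fitness_components()` estimates the three components in the units
of the study's figures (hours, OD), with log2 transforms. The default
estimator linearizes logistic growth exactly on the logit scale
($\ln(x/(K - x))$ is linear in $t$), estimating the plateau $K$ from the top
smoothed readings and pooling every reading between 0.02 OD and 90% of $K$
into one OLS fit; the lag is where the fitted line crosses the logit of the
inoculum reference density (default $10^{-3}$ OD — for real data set
`ref_level` to the known inoculum signal). The classical tangent
construction (maximal sliding-window slope of log size, lag from the
tangent's intersection with the inoculum level) is available as
`method = "max-slope"`; it makes no shape assumption beyond early
exponential growth but is much noisier — at plate-reader-like noise
(SD 0.003 OD at 20-min cadence) its median doubling-time error is ~6%
against ~1% for the logistic estimator, which is why the latter is the
default. Founder normalization follows the orientation conventions that
make positive relative values always mean adaptation: founder-mean log2
minus experimental log2 for lag and doubling time, and the reverse for
efficiency; replicate means are taken after the log2 transform.

One honest caveat: the synthetic generator produces logistic-with-lag
curves, so validating the logistic estimator against it is partly circular.
The round-trip tolerances (median doubling-time error under 5%, lag within
one 20-min sampling interval over 200 noisy draws) demonstrate noise
robustness and unit correctness, not robustness to real curves'
departures from logistic shape (diauxie, death phases, drift); for such
data the max-slope method is the appropriate cross-check.

## Small estimators

* `fluctuation_mutation_rate()`: the p0 method, $\mu = -\ln(P_0)/N$, with
  the degenerate $P_0 = 0$ case signalled (repeat at higher dilution).
* `standing_variant_probability()`: a clonal expansion to $n$ cells entails
  $n - 1$ divisions; adaptive mutations are Poisson, so a founder clone
  carries a standing variant with probability $1 - e^{-\text{rate}\,(n-1)}$,
  and all of $k$ independent clones do with that probability to the $k$-th
  power. The beneficial rate is an explicit input: naively adding the
  duplication channel's $3\times10^{-7}$/division would predict
  near-certain standing duplications over $3\times 10^7$ divisions, so the
  choice of which channels count is left to the caller.
* `filter_variant_trajectories()`: the sequencing confidence gate — total
  read depth > 100 (summed over time points by default; a per-time-point
  mode exists because the phrasing admits both readings), frequency > 10%
  at two or more time points, and SIFT < 0.05 when scores are present. The
  filter is idempotent and monotone in its thresholds.

## Synthetic data

All pipeline inputs are generated in code: logistic-with-lag growth curves
with additive Gaussian reading noise (logistic rather than the model's pure
lag + exponential so that plateau/efficiency extraction is exercised),
plates with founder controls at randomized recorded positions, and variant
tables with Poisson depths and binomial alternate reads. Defaults emulate
the study's cultivation: 72 h at 20-min cadence, background 0.08 OD, noise
SD 0.003 OD, inoculum $10^{-3}$ OD. Every generator is deterministic under
a fixed seed and its output parses through the corresponding reader.

## Problem sizes used by the test suite

The packaged tests run the deterministic analyses at full study scale
($N = 10^5$, 20 cycles), the competition IBM at 25 and 1000 replicates, the
rate scan at 25 replicates $\times$ 4 multipliers $\times$ 50 cycles, and
the pleiotropy sweep on a seeded 50-set subsample of the 750-set grid —
sizes chosen so the whole suite completes in a few minutes while keeping
every stochastic comparison at its stated replication. Unit tests use
smaller bottlenecks where only the event rules, not the published
quantities, are at stake.

## Known limitations

* Synchronous-division quantization (above) biases within-cycle gains
  relative to the continuum model; conclusions that depend on fractional
  division counts should use `compete_deterministic()`.
* No death, dormancy, diauxie, interactions, diploidy or recombination.
* The $\beta \to s_r$ bridge and the genome size $G$ are interpretive
  choices; sweep-level counts shift with them even though the M1/M2/M3
  ordering is robust.
* Allele classes in the targeted model are abstract labels with rates and
  effects; no sequence-level mutation is simulated.
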