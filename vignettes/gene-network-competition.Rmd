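---
title: "Eco-evolutionary competition between Boolean gene-network traits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary competition between Boolean gene-network traits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grncompete)
```

## The question

How does the genetic architecture of an ecologically critical trait — in
particular the *size* of the gene network that encodes it — shape the outcome
of interspecific competition when the environment changes? Small networks
divide the trait among few genes, so each heritable change moves the
phenotype a long way: they adapt *fast* but *coarsely*. Large networks divide
the trait finely: they adapt *accurately* but hold less usable additive
variance. `grncompete` is an individual-based, forward-time simulator built
to expose this speed-versus-accuracy tradeoff in a two-species competition
under a steadily moving environmental optimum, together with the statistical
machinery used to summarise it.

## The genotype-phenotype map

Each individual carries one heritable chromosome that encodes a directed
Boolean regulatory network of `n` genes. Gene 1 (the root) carries only a
heritable on/off state. Every other gene carries a two-part block: the index
of its single regulator (`head`) and a function bit (1 = activator,
0 = repressor). Since each non-root gene contributes exactly one incoming
edge, out-degrees always sum to `n - 1` and at least one *terminal* gene
(out-degree 0) exists in every chromosome, including after mutation.

States propagate from the root: a gene is "on" exactly when its regulator's
state equals its function bit (an XNOR) — an "on" activator or an "off"
repressor switches its target on; an "on" repressor or an "off" activator
switches it off. The phenotype is the fraction of terminal genes that are on,
scaled to the environmental range of 140:

```{r}
chr <- fixture_fig_network() # 13 genes, 8 terminal, 4 of them on
phenotype(chr)               # 140 / 8 * 4
```

A network with `T` terminal genes can only realise the `T + 1` values
`140 k / T`: **trait resolution is the accuracy cost of a small network.** A
16-gene network typically has ~8 terminals (steps of ~17.5 units); a 256-gene
network ~128 (steps of ~1.1 units).

Topologies are grown sequentially. Under `"random"` attachment, gene `i`
attaches below a uniform choice of genes `1..i-1`; under `"scale_free"`, with
probability proportional to (current out-degree + 1). The `+1` keeps
zero-degree genes attachable, since pure proportionality would freeze growth
at the first step; the implementation uses the exact O(1)-per-draw
equivalent (attach uniformly with probability `(i-1)/(2i-3)`, otherwise copy
the head of a uniformly chosen existing edge).

Two deliberate choices concern edge cases the encoding allows:

* **Cycles.** Regulator mutations can detach a set of genes into a cycle
  unreachable from the root. Such genes are assigned state 0,
  deterministically. The alternative — iterating cycle states to a fixed
  point — was rejected because cycle attractors depend on evaluation order
  and would make the phenotype non-deterministic.
* **Self-regulation** is excluded everywhere, including on mutation redraws:
  a self-loop would be permanently dead weight under this propagation rule.

## Inheritance

Reproduction is sexual, between hermaphrodites, with non-overlapping
generations. The offspring chromosome is built from the element sequence
`[root state, gene-2 block, ..., gene-n block]`, with each gene's
(regulator, function) pair inherited as one block: the parent supplying the
first element is chosen by a fair coin, and before every subsequent element
the source parent switches with probability `r` (the recombination rate).
Each block then mutates independently with probability `mu`; a mutating
block either flips its function bit or redraws its regulator uniformly among
all other genes, with equal probability — the two mutation kinds are not
weighted because there is no principled basis for asymmetry. The root state
recombines but never mutates.

## The life cycle and selection

Each generation, every individual initiates one mating with a partner drawn
uniformly from the rest of its population (no selfing; an individual may be
chosen as partner repeatedly). Each mating yields `Poisson(1.5)` offspring.
Death then comes in three stages: all parents die; each offspring survives
viability selection with probability equal to its *relative fitness*

\[ RF = \exp\!\left(-\frac{\Delta^2}{2\omega^2}\right), \qquad
   \Delta = |E - z|, \]

where `E` is the environmental optimum, `z` the phenotype and `omega` the
selection breadth in trait units; finally, if survivors exceed the carrying
capacity `K = 500`, uniformly random individuals are removed. RF gates
survival only, never fecundity.

**Why one-mating-per-initiator?** The obvious alternative — shuffling the
population into disjoint pairs — halves the number of matings and caps the
per-capita growth factor at `1.5 / 2 = 0.75` *before* selection, which makes
every population shrink deterministically to extinction within tens of
generations. One initiated mating per individual gives per-capita fecundity
1.5, the smallest scheme under which a well-adapted population can actually
replace itself.

**Why `omega = 20`?** The breadth is the one parameter whose scale the model
family leaves genuinely under-determined, and the default was fixed by a
one-time calibration against the model's own viability arithmetic, not by
tuning to any test. Mean fitness of a population with phenotypic variance
`V_P` centred on the optimum is at most `omega / sqrt(omega^2 + V_P)`, so
with fecundity 1.5 a population is only demographically viable (growth
`1.5 × meanRF ≥ 1`) when `omega ≥ 0.9 sqrt(V_P)`. Random founding produces
`V_P` in the hundreds for small networks: breadths of a few trait units
make *every* architecture non-viable (we measured 0–1 canalization
survivals in 12 at `omega = 2`, the survivors only via collapse to
monomorphism), and breadths around 10 leave the 16-gene, `r = 0.5`
architecture passing canalization only through a variance-destroying
bottleneck that hands it an artificial fitness advantage ever after.
`omega = 20` is the smallest round value at which every studied
architecture canalizes *without* collapse, while the emergent additive
variance still declines with network size at realistic magnitudes (~30
squared units for 16 genes down to ~4 for 256) and the tracking threshold
`V_A ≳ 1.1 × dEdt × range × omega ≈ 25` keeps the fastest environmental
rates lethal precisely for the large, low-`V_A` networks. `omega` remains
a configurable argument everywhere.

## Environment

A single scalar optimum starts at 70 and moves directionally within
`[0, 140]`, reflecting off the boundaries; all patches share the identical
trajectory. `environment_state()` takes its rate in plain trait units per
generation; the *protocol* layer (`competition_config()`) takes the
treatment rate `dEdt` as a fraction of the environmental range per
generation and steps the optimum by `dEdt * env_range`. The distinction
matters: on the range-fraction scale the studied grid spans 1.12 trait
units per generation (a fluctuation that sweeps the range several times in
a 1000-generation run — fast enough that only architectures holding
`V_A` of roughly `dEdt * env_range * omega^2 / 9 ≈ 12+` squared units can
track it) down to 0.028 units per generation (nearly static, where fine
trait resolution pays). Read literally as raw units per generation the same
grid would move the optimum at most 8 units in 1000 generations — under
0.1 `omega` over any initial-competition window — and no rate effect of
any size could arise; the range-fraction reading is the only one on which
the rate treatments can do selective work on these horizons.

## The competition protocol

`run_competition()` executes, under a single seed:

1. **Canalization** — each species alone in its own patch, founded by
   `K = 500` random genotypes, evolving for 20 generations. This purges the
   enormous founding variance. Founding at `K` is the natural saturated
   start; the true initial census is not otherwise determined. A species
   that dies during canalization invalidates the attempt, and the run is
   re-seeded deterministically (the attempt count is reported).
2. **Dispersal** — 200 random survivors of each species move to a third
   patch; everyone else dies. A bottlenecked species with fewer than 200
   survivors disperses whole, with a warning.
3. **Competition** — both species reproduce and face viability selection
   against the same optimum, then one *pooled* carrying capacity `K = 500`
   culls the community without regard to species: the two species are
   neutral with respect to resource *quantity* (identical requirement and
   impact), and compete through adaptation to resource *quality*. Pooled
   rather than per-species culling is what co-limitation means here.
4. The run ends at the first extinction, or is censored at 1000 competition
   generations, in which case the larger final population wins (exact ties,
   and simultaneous extinctions, are broken by a fair coin).

Outcomes per run: the OLS slope of focal population size over the first 20
competition generations (`dNdt_slope`, the competitive-impact metric), the
winner, the time to resolution, and both species' variance components at
the start of competition.

The default focal species is the fixed reference architecture — 16 genes,
scale-free topology, `mu = 1e-3` and `r = 0.05`. The low focal
recombination rate matters: at `r = 0.5` the constant reshuffling of
whole-gene blocks between unrelated 16-gene networks keeps the focal's
phenotypic variance so high that its own early-competition growth is
depressed at the fastest environmental rates, drowning the treatment
signal; at `r = 0.05` the focal canalizes properly and the competitor's
architecture is what varies. The competitor's recombination rate is a
treatment (0.05 or 0.5), so the focal-versus-16-gene-competitor cells are
deliberately asymmetric in half the design.

## Emergent quantitative genetics

Heritability is estimated each generation by mid-parent regression — the
OLS slope of offspring phenotype on the mean of its parents' phenotypes —
computed over the post-selection survivors (the individuals that exist),
clamped into `[0, 1]` because drift and sampling can push the raw slope
outside the meaningful range and a negative additive variance has no
interpretation. `V_P` is the sample variance of phenotypes and
`V_A = h2 × V_P`. These are emergent properties of the evolving networks;
nothing in the simulator specifies them.

## Downstream statistics

The analysis layer reproduces the factorial summaries on the run table:
`sequential_anova()` (Type-I sums of squares in the stated term order, with
percent variance per term — sequential decomposition is what a single
ordered percent-per-term table implies), `winner_glm()` (binomial GLM with
logit link, sequential analysis of deviance, which telescopes exactly from
the null to the residual deviance), `log_ttr_model()` (times are
right-skewed, so the response is log-transformed), and `aic_select()`
(standard AIC, not AICc, given the sample sizes). Treatments — including
`dEdt` — enter as unordered factors; emergent variance components enter as
continuous covariates. Censored runs are kept in the winner and
time-to-resolution analyses at the cap value.

## What the simulator does and does not emulate

The generator *is* the study system: there is no external data. It emulates
heritable regulatory architecture, recombination and mutation at the level
of network elements, hard Gaussian viability selection, and co-limitation in
a shared patch. It does not emulate: multiple regulators per gene,
continuous expression levels, pleiotropy across traits, environmental noise
in the optimum, age structure, fecundity selection, or resource depletion.
Conclusions from passing tests are therefore statements about this model
family, not about any natural population.

## Problem sizes and reproducibility

The test suite and the acceptance script run reduced-scale designs chosen
once as the package's desk-scale study conditions: 40-generation runs
(20 canalization + 20 competition) for the initial-competition factorial
(5 network sizes × 2 recombination rates × 5 rates of change, 5
replicates), 200 replicate seeds for the symmetry check at a 200-generation
cap, and 20-replicate sentinels at the fast/slow extremes for the winner
and time-to-resolution structure. Every run's randomness flows from one
31-bit seed derived by hashing the base seed with the treatment labels and
replicate index, so any row of any sweep can be reproduced in isolation.

## Known limitations

* At breadths near the viability boundary, the 16-gene high-recombination
  architecture passes canalization through a bottleneck; its post-dispersal
  populations are occasionally near-monomorphic, which makes its mid-parent
  heritability estimate undefined in some runs (reported as `NA` and
  dropped by the variance-component models).
* Resolution of competition at the desk scales is often fast (tens to a few
  hundred generations); long-horizon coexistence behaviour is only probed
  by the slow-rate sentinels.
* The sequential (Type-I) decomposition makes the percent-variance entries
  order-dependent; the term order follows the factorial analyses it
  mirrors.
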