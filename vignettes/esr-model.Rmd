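---
title: "The esrsim model: feeding-cycle population genetics of evolved spatial repellents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The esrsim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esrsim)
```

## The idea being modelled

An evolved spatial repellent (ESR) programme pairs a candidate repellent —
initially able to deflect only part of a vector population away from treated
houses — with a high-toxicity indoor insecticide. The insecticide kills
non-deflected entrants, so it selects for the deflection trait; as deflection
spreads, the repellent's efficacy grows, and the insecticide is shielded from
resistance because deflected mosquitoes never contact it. `esrsim` asks when
that positive feedback wins against the competing spread of physiological
resistance.

## Genetic model and assumptions

Two autosomal bi-allelic loci, unlinked (recombination fraction 1/2):
resistance (*r*/*R*) and deflection (*d*/*D*), both with the derived allele
completely dominant. The model's structural assumptions are:

1. single-locus dominant control of each trait;
2. free re-assortment between the loci;
3. deflected phenotypes never contact the insecticide, so (under
   full co-deployment) resistance confers no benefit to them;
4. genotype does not affect juvenile survival;
5. random mating, females mating once at emergence with males of their own
   recruitment cohort;
6. juvenile density dependence strong enough that adult recruitment is a
   constant number per cycle, whatever the egg input.

Genotypes are stored unphased (9 states). This loses nothing: at
recombination fraction 1/2 the cis and trans double heterozygotes emit
identical gamete distributions, so phase is unobservable anywhere in the
model.

## The analytic layer

For a gamete pool `h` (haplotype frequencies over `rd`, `rD`, `Rd`, `RD`)
and phenotype survivals `f`, `mean_offspring_fitness_deflection()` and
`mean_offspring_fitness_resistance()` give the mean per-cycle survival of
offspring classed by which allele they inherit. The deflection allele
spreads over one round of random mating and selection exactly when
`Fbar_D > Fbar_d` (`deflection_spread_predicate()`); equality is resolved as
*no spread*, since a strict fitness advantage is what the strategy relies
on. When the focal allele is absent or fixed the comparison is undefined and
the predicates return `NA` rather than `FALSE` — callers must branch, which
keeps "cannot spread" distinct from "nothing to spread".

Two limiting reductions anchor intuition and are tested: with no resistance
alleles the deflection condition collapses to `F_D > F_S`, and at deflection
fixation the resistance condition collapses to `F_RD > F_D`.

Every closed form is checked against `brute_force_offspring_fitness()`, an
independent 16-pairing enumeration that weights each zygote by its pairing
probability times the copies of the focal allele it carries; agreement is
required to 1e-12 over 1000 random pools and fitness vectors.

`generation_step()` is the matching *non-overlapping-generations* recursion
(random union, one round of viability selection, reproduce, die). It is the
right object for analytic cross-checks: under neutrality it conserves allele
frequencies exactly and halves linkage disequilibrium each generation, and
the sign of its one-generation change in D frequency equals the spread
predicate. The full simulator below deliberately does *not* have
non-overlapping generations, which matters for time scales (see "Numerical
behaviour").

## The feeding-cycle simulator

Each time unit is one gonotrophic cycle. Within a cycle, events are ordered:

1. **survive** — every adult survives with her phenotype's per-cycle
   probability (mode-dependent: see below);
2. **feed / incubate** — surviving uninfected adults acquire *Plasmodium*
   with their phenotype's per-feed probability; incubating adults advance
   one cycle; a mosquito infected at feed *t* is infectious from feed
   *t + incubation_cycles* inclusive;
3. **bite** — infectious surviving feeders emit `count × p_infectious_bite`
   infectious bites (bites are counted *after* that cycle's survival, a
   choice recorded in every run's metadata);
4. **oviposit** — each surviving female contributes one unit of zygotes,
   her gametes crossed with her stored sperm pool, every cycle;
5. **recruit** — the zygote pool laid `development_cycles` ago emerges as
   `recruits_per_cycle` new adults, mated immediately within their cohort.

Neither the within-cycle event order nor whether oviposition happens on
every feed is dictated by the biology at this level of abstraction; both
choices here are the simplest consistent ones and are fixed, not
configurable, so results are comparable across scenarios.

**State representation.** Conceptually the population is cohort-structured
(genotype × emergence cohort × infection stage, each cohort with a frozen
sperm pool). Because survival and infection depend only on genotype, and a
female's offspring are linear in her sperm pool, the implementation tracks
two exact linear aggregates instead: counts by (genotype × stored-sperm
haplotype) for reproduction and counts by (genotype × infection stage) for
transmission. This is an exact reduction, not an approximation, and makes a
300-cycle run cost a few milliseconds, which the grid scans rely on.

**Intervention modes.** `esr_plus_insecticide` applies
(`F_S`, `F_R`, `F_D`, `F_RD`); `none` applies the no-treatment survival `U`
to everyone; `insecticide_only` removes the repellent, so deflected
phenotypes revert to their exposure class (`F_D → F_S`, `F_RD → F_R`). The
latter mapping assumes the costs of resistance are zero, which holds in
every shipped scenario that uses the mode; with a nonzero `COR₂` the
treatment table would give `U − COR₂` instead. `U` is identified with `F_R`
when no cost of resistance applies — the treatment table's resistant row
averages to `U` — and that identification also sets the pre-intervention
equilibrium population `recruits_per_cycle / (1 − U)` used to initialize
runs. Acquisition probabilities follow deployment, not genotype: the
deflected acquisition probability applies only while the repellent is
actually deployed.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `F_S, F_R, F_D, F_RD` | 0.20, 0.60, 0.45, 0.45 | per-cycle survival probability of each phenotype |
| `init_R_freq, init_D_freq` | 0.005, 0.25 | initial allele prevalences (Hardy–Weinberg, linkage equilibrium) |
| `p_acquire_nondeflected` | 0.04 | per-feed probability of acquiring *Plasmodium* |
| `p_acquire_deflected` | 0.04 | same for deflected phenotypes under the repellent; reductions proxy *all* sources of lower outdoor transmission |
| `p_infectious_bite` | 0.8 | per-feed probability an infectious mosquito bites a human infectiously |
| `incubation_cycles` | 3 | extrinsic incubation, in feeding cycles |
| `development_cycles` | 3 | egg-to-adult delay, in feeding cycles |
| `recruits_per_cycle` | 100 | adult recruitment under density dependence; pure scale, cancels from every proportional output |
| `n_cycles` | 300 | horizon; also the default establishment read-out cycle |

The survival defaults correspond, through the treatment table, to full
co-deployment (`Y₄ = 1`): e.g. `U = 0.6`, `I = 0.4`, `B = 0.15` reproduce
20/60/45/45%. Establishment means ≥ 80% deflected phenotypes (deflected +
resistant-deflected — both carry *D* and are repelled) at the read-out
cycle; a tie at exactly 80% counts as established.

## Scenario fixtures and the random generator

The named fixtures (`list_scenarios()`) encode the package's study
conditions: the baseline above; `transient` (deflected survival 40%, spread
then collapse); `failure` (additionally susceptible survival 30%, initial
R 5%, D 10%); and the grid-scan variants `low_init_deflection` (D 10%),
`high_init_resistance` (R 2%), `high_susceptible_survival` (F_S 60%).
`timeseries_panel_scenario("a".."c")` and `grid_panel_scenario("i".."iv")`
expose the same sets by panel.

`random_scenario(seed)` draws survivals uniformly in [0.05, 0.95] and
allele frequencies in (0.01, 0.99) for property tests — wide enough to probe
the algebra well outside the plausible region, while every draw still passes
the validators. It restores the caller's RNG state, so fixtures never
perturb downstream randomness.

What the deterministic model emulates — and what it does not: it captures
selection, dominance, the recombination lag between the loci, delayed
recruitment and the incubation delay. It has no drift (infinite-population
assumption), no immigration or spatial structure, no seasonality, and no
human infection dynamics (the output is entomological only). Passing tests
therefore say nothing about stochastic loss of rare alleles in small
populations or about rescue by immigration, both of which matter in the
field.

## The experiments

* `grid_scan()` classifies each (resistant survival × deflected survival)
  cell as `direct`, `ratchet`, or `fail` at 1% increments; default extents
  30–70% × 20–60% (the increments are fixed by convention, the extents are
  configurable).
* `ratchet_run()` simulates replacing the partner insecticide once, at the
  cycle where the deflection allele peaks: a fresh run initialized at that
  D prevalence with 0.5% resistance alleles (linkage equilibrium,
  re-initialized cohorts). By default the second run is classified 300
  cycles *after the swap* — the swap is a fresh introduction of a new
  insecticide; `clock = "from-start"` instead counts the original clock
  down, for readers who prefer a fixed programme horizon.
* `min_cor_scan()` finds, per cell, the smallest cost of resistance on the
  resistant-deflected phenotype (`F_RD = F_D − COR`) that rescues
  establishment, without any ratchet; `NA` marks cells no tested cost
  rescues.
* `blended_fitness()` models incomplete deflection
  (`F_RD = w·F_D + (1−w)·F_R`, default `w = 0.75`).
* `relative_bites_experiment()` compares infectious bites per cycle — relative to a
  no-intervention baseline — for the unpaired insecticide and for the
  ESR + insecticide combination at deflected acquisition probabilities 4%,
  2%, 1%, 0%.

## Numerical behaviour, tolerances, degenerate inputs

* All distributions are renormalized only at zygote pooling; conservation is
  a test invariant (1e-12 per cycle on distributions, 1e-9 over 300 cycles
  on allele frequencies under neutrality).
* Ratios to the baseline are `NA` during the initial transient (before the
  baseline's infectious class is populated, i.e. the first
  `incubation_cycles + 1` feeds); a zero baseline after the transient is an
  error, not an `Inf`.
* An empty population (all survivals 0) is a zero-emission steady state,
  not an error.
* Establishment time scales: with overlapping generations one feeding cycle
  is *less* than one generation of selection (roughly 5 cycles per
  generation at the default survivals). Consequently the approach to
  fixation of *D* in cycle units is slower than the discrete-generation
  recursion in generation units, and the first few cycles can show a small
  (~1e-3) non-monotonicity in adult allele frequency while the pre-filled
  juvenile queue — laid before the intervention changed anything — clears.
  Tests assert monotone spread from the end of that transient onward.
* Proportions are written to CSV at 12 significant digits so that repeat
  runs can be compared byte-for-byte; every output directory carries a
  `metadata.json` echo sufficient to rebuild the run exactly.

## Problem sizes used by the test suite

Unit tests run sub-grids of 1–9 cells and horizons of 20–300 cycles; the
acceptance checks use the full 300-cycle horizon, a 10×10 grid around the
(60%, 45%) reference cell, 1000-draw oracle comparisons and 200-draw
predicate/simulation agreement sweeps. A full 41×41 production grid with
ratchet retries takes on the order of a minute.

## Known limitations

* Deterministic, infinite-population dynamics only; no drift, so alleles are
  never lost at low frequency, and rare-allele results are optimistic.
* Single environment: no property-mix heterogeneity beyond the static
  `Y₁–Y₄` weights, no immigration, no seasonality.
* Deflection and resistance are binary, fully dominant, single-locus traits;
  polygenic or continuous deflection would change the establishment
  dynamics.
* The repellent's epidemiological benefit enters only through the deflected
  acquisition probability (and the survival cost `B`); onward human
  infection is out of scope.
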