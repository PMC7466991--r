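---
title: "Modelling brake countermeasures against CRISPR homing gene drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling brake countermeasures against CRISPR homing gene drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivebrake)
```

## The question

A CRISPR homing gene drive converts the homologous wild-type allele into a
drive copy, so it can sweep through a population even while imposing a large
fitness cost.  An *eradication* drive is designed so that a drive-fixed
population is not viable.  One proposed countermeasure is a *brake*: a
cas9-devoid construct whose guide RNA targets the drive's *cas9*, so that in
drive/brake heterozygotes the drive allele is converted into a brake copy,
while the wild-type allele is left untouched.  `drivebrake` asks whether
releasing brake carriers can rescue a population already invaded by an
eradication drive, and under what drive and brake characteristics.

Because an eradication drive collapses the population while it spreads,
allele frequencies and population density feed back on each other.  The
model therefore tracks *densities* of the six diploid genotypes formed by
the wild-type (0), drive (D) and brake (B) alleles, rather than frequencies
alone.

## The model

For each genotype $g \in \{00, 0D, DD, 0B, DB, BB\}$ with density $N_g$
(total $N = \sum_g N_g$), zygote survival $\omega_g$, adult death rate
$d_g$ and fecundity $\beta_g$,

$$\frac{dN_g}{dt} = \omega_g V_g N\left(1 - \frac{N}{K}\right) - d_g N_g,$$

where $K$ is the carrying capacity of the logistic birth term and $V_g$ is
the rate at which genotype-$g$ zygotes are produced by random union of
fecundity-weighted gametes: with $x_a = \sum_g \beta_g (N_g/N)\,
\gamma_g(a)$ the flux of allele-$a$ gametes ($\gamma_g$ the gamete
distribution of genotype $g$), $V_{aa} = x_a^2$ and $V_{ab} = 2 x_a x_b$.
Reproduction is density dependent; mortality is not.  Births are clamped at
zero for $N \ge K$: the logistic factor would otherwise turn negative,
which is unphysical and has no stochastic counterpart.  The population is
monoecious, unstructured and randomly mating.

Gene conversion acts at one of two life-cycle stages:

* **germline** — heterozygote gametes are biased: a $0D$ individual
  transmits $D$ with probability $(1+c_D)/2$, a $DB$ individual transmits
  $B$ with probability $(1+c_B)/2$.  A $0B$ individual segregates 50:50
  because the brake does not cut the wild-type allele.
* **zygote** — gametes are Mendelian, but newly formed $0D$ and $DB$
  zygotes are converted into $DD$ and $BB$ homozygotes with probabilities
  $c_D$ and $c_B$, and carry the homozygote's traits from the zygote stage
  on.  In `zygote_production()` this is a transfer between zygote classes
  that conserves $\sum_g V_g = (\sum_a x_a)^2$; the conservation is tested
  against a brute-force enumeration of all 36 ordered parental pairs.

Heterozygote traits are linear in a shared dominance coefficient $h$:
$\omega_{0D} = (1-h)\,\omega_{00} + h\,\omega_{DD}$,
$\omega_{0B} = (1-h)\,\omega_{00} + h\,\omega_{BB}$,
$\omega_{DB} = (1-h)\,\omega_{BB} + h\,\omega_{DD}$, and likewise for $d$
and $\beta$.

### Scenario standardisation

Drive and brake costs act on exactly one trait — zygote survival
($\omega$), adult death rate ($d$) or fecundity ($\beta$) — with all other
traits equal across genotypes.  The drive homozygote's value of the
targeted trait solves

$$\frac{d_{DD}}{\omega_{DD}\,\beta_{DD}^2} = 1.1,$$

so that a 100% drive population is not viable whatever trait is targeted
(the analogous wild-type ratio must be below 1 for the base population to
be viable; the wild-type-only equilibrium is
$N^* = K\,(1 - d_{00}/(\omega_{00}\beta_{00}^2))$).  A *universal* brake
carries no cargo: the $BB$ genotype has exactly the drive homozygote's
traits.  A *specific* brake carries a recoded copy of the disrupted gene
and recovers a fraction `restoration` (default 0.95) of the wild-type/drive
gap on the targeted trait, leaving a small residual cost relative to wild
type.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| $\omega_{00}, \beta_{00}$ | 1 | wild-type zygote survival, fecundity |
| $d_{00}$ | 0.1 | wild-type death rate (mean adult lifespan 10 time units) |
| $K$ | $10000/0.9$ | chosen so $N^* = 10000$ |
| $c_D, c_B$ | 0.95 | conversion probabilities |
| $h$ | 0 | costs fully recessive |
| `drive_intro` | 100 | $0D$ heterozygotes added at $t = 0$ |
| `N0B` | 100 | $0B$ heterozygotes released at the trigger |
| $f_I$ | 0.5 | drive frequency triggering the brake release |

The conversion default of 0.95 reflects the high homing efficiencies of
laboratory eradication drives and, together with recessive costs and
germline conversion, makes the default drive threshold-independent — the
release scenario the brake literature is most concerned with.  How the
drive enters the population is a modelling choice: runs start from the
wild-type equilibrium plus `drive_intro` drive heterozygotes.

## Deterministic solutions

`run_deterministic()` advances the system by explicit Euler steps of fixed
size `dt = 0.005`.  A higher-order stepper would interact awkwardly with
the two discrete mechanisms that act at step boundaries, so Euler is the
reference scheme; halving `dt` changes trajectories by well under 0.1%
(tested).  The two mechanisms are:

* **critical density** `thr = 0.01`: after every step, any genotype below
  `thr` is set to zero.  The brake triggers oscillations of large
  amplitude in which genotype densities fall to values that are
  biologically meaningless (fractions of one individual) and numerically
  dangerous (underflow); truncation converts those excursions into allele
  loss.  `thr = 0` disables truncation and recovers the pure
  infinite-population model, in which no allele is ever lost in the
  oscillations.  Which alleles survive under truncation depends on `thr`
  and `dt` — a non-biological contingency that the stochastic engine
  removes.
* **brake release**: at the first step boundary (including $t = 0$) where
  the drive allele frequency $p_D$ reaches $f_I$, `N0B` wild-type/brake
  heterozygotes are added, once.  If $p_D$ never reaches $f_I$ the release
  never happens.

Genotype updates are componentwise, so simultaneous truncations need no
tie-breaking.  Extinction ($N = 0$) is absorbing.  Runs are classified at
`tmax` (default 25000; the outcome sweeps below use 2500, which is ample
for outcome resolution at desk scale) or at total extinction into: wild-type
recovery, coexistence of wild type with brake (or with drive and brake),
extinction before/after the release, drive loss before the release, or —
honestly — `undetermined_at_tmax`.

Each state is also reported in the reformulated coordinates used for the
analysis: total density $N$, allele frequencies
$p_D = (N_{DD} + \tfrac12 N_{0D} + \tfrac12 N_{DB})/N$ (and $p_B$
analogously), and Hardy–Weinberg deviations such as
$\delta_{0D} = N_{0D}/N - 2 p_D p_0$.  In this continuous-time,
overlapping-generations model the deviations cannot be neglected, and the
reformulation makes the eco-evolutionary feedback explicit: conversion
happens at reproduction, reproduction is density dependent, so allele
frequency change slows as $N$ grows.

## Stability analysis and the four drive categories

All stability statements are numerical: the reduced right-hand side (in
$N$, frequencies, deviations) is obtained from the density system by the
chain rule, differentiated by central differences, and its eigenvalues
examined.  An equilibrium is stable when all real parts are below
$-\varepsilon$ with $\varepsilon = 10^{-7}$; verdicts within $\varepsilon$
of zero are reported as *marginal*, never silently classified, and are
settled by a perturbation–integration oracle (this matters for fully
recessive costs with no conversion, where invasion fitness is second
order).

In the two-allele (no brake) model the boundary equilibria are the
wild-type-only state $(N^*, p_D = 0, \delta_{0D} = 0)$ and, for an
eradication drive, the drive-only state $N = 0$, $p_D = 1$.  At the
extinction boundary the reduced frequency coordinates survive the collapse
($N \to 0$ makes the logistic factor 1), so the drive-only boundary is
analysed in the vanishing-density frequency system; the verdict is
corroborated by integrations seeded with a trace of wild type.  The four
combinations of boundary stabilities give the four drive categories —
*loss*, *coexistence*, *fixation*, *bistability* — and only bistable
drives are threshold-dependent.  For those, `invasion_threshold()` locates
the separatrix by bisection on the introduction frequency (Hardy–Weinberg
introduction into the wild-type equilibrium, bracket tolerance $10^{-3}$),
and the result is corroborated, where one exists, by a located unstable
interior equilibrium.  For eradication drives the bistable separatrix
often meets the extinction boundary, in which case no positive-density
interior equilibrium exists and only the bisection threshold is reported.

The package's central analytic statement, tested across hundreds of random
scenarios, is that brake parameters never change the local stability of
the wild-type-only equilibrium: the brake can only rescue populations
whose drive would already fail to reinvade a recovered wild-type
population — in practice, threshold-dependent drives.  Under truncation
(`thr > 0`) or stochasticity, however, threshold-*independent* drives can
also be stopped, because the oscillations after the release push
drive-carrying genotypes below one individual.

## The stochastic engine

The Gillespie implementation translates the ODE directly into a jump
process: twelve propensities — births per genotype
$\omega_g V_g N \max(0, 1 - N/K)$ with $V_g$ computed on the count vector,
and deaths $d_g n_g$ — with exponential waiting times and
propensity-proportional event choice, recomputed after every event (exact
SSA; all six genotype classes carry propensities).  Counts are integers, so
allele loss is intrinsic and no critical density is needed.  Initial counts
are the rounded wild-type equilibrium plus `drive_intro` heterozygotes; the
release adds `N0B` integer $0B$ individuals at the first event boundary
where $p_D \ge f_I$.  Replicate $i$ of an ensemble uses seed
`base_seed + i - 1` under R's default Mersenne–Twister generator, making
ensembles bitwise reproducible; replicates run serially so thread count
cannot change results.

Exactness is tested distributionally (event-choice shares, waiting-time
mean, and the closed-form pure-death extinction law
$P(T \le t) = (1 - e^{-dt})^{n_0}$) and through the fluid limit: scaling
$K$ tenfold brings the ensemble mean measurably closer to the ODE
solution.

## Scenario grid and sweeps

`scenario_grid()` enumerates the factorial 2 timings × 3 traits × 2
dominance values (0, 0.5) × 2 brake kinds = 24 combinations;
`sweep_introduction()` runs, per release frequency $f_I$, a stochastic
ensemble and one deterministic run, in long form, and
`wt_recovery_trend()` summarises the (usually decreasing) trend of
recovery with later release.  Under the package defaults the 24
combinations span several drive categories — zygote-timing combinations
are mostly threshold-dependent, which is itself a known structural feature
of zygote conversion — so sweeps that specifically concern
threshold-independent eradication drives use the germline fixtures.

## Problem sizes used in the tests

The test-suite and example defaults are desk scale, chosen to keep the
full suite in minutes while leaving every qualitative contrast intact:
$N^* = 500$ and 200 replicates for the brake-comparison ensembles (the
full-scale $N^* = 10000$ with $10^4$ replicates remains configurable),
outcome horizons of 2500 time units, and 200 random scenarios for the
stability-agreement property.  The synthetic scenarios emulate the
standardised eradication-drive setting only: one locus, no sex structure,
no resistance evolution, no spatial structure, no conversion failure
products (non-homologous end joining).  Passing tests therefore say
nothing about those processes; they validate the eco-evolutionary feedback
mechanism, the conversion genetics, and the exactness of the simulators.

## Known limitations

* Outcomes of truncated deterministic runs depend on `thr` and `dt` by
  design; they reproduce the *kind* of outcome diversity seen in the
  stochastic model, not replicate-level frequencies.
* The drive-only boundary analysis assumes an eradication drive
  (`drive_ratio > 1` is enforced); replacement drives are outside the
  package's scope.
* Near category boundaries in parameter space the leading eigenvalue
  passes through zero and verdicts there are reported as marginal rather
  than forced.

## A worked example

```{r example, eval = FALSE}
sc <- gdrive_scenario(N_star = 500, tmax = 2500)   # desk scale
classify_drive(sc, find_threshold = FALSE)$category
#> "fixation"                                       # threshold-independent

ens_univ <- simulate(sc, nsim = 200, seed = 1)
ens_spec <- simulate(gdrive_scenario(N_star = 500, tmax = 2500,
                                     brake_kind = "specific"),
                     nsim = 200, seed = 1)
outcome_tally(ens_univ)   # extinction remains frequent
outcome_tally(ens_spec)   # drive always lost; wild type often recovered
```
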