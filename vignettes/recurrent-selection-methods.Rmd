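---
title: "Simulating recurrent genomic selection with variance-preserving mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recurrent genomic selection with variance-preserving mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscope)
```

## The problem

Genomic selection programs that pick parents purely by truncation on genomic
estimated breeding values (GEBVs) gain quickly at first and then stall: small
favorable QTL alleles, invisible inside a single aggregate GEBV, drift out of
the breeding population and fix on the wrong allele. Once an unfavorable
allele is fixed it is gone for good — no amount of later selection recovers
it — so the *maximum reachable genetic value* of the program decays
irreversibly. `gscope` simulates a recurrent selection scheme for a fully
inbred crop and compares four parental selection strategies that trade
short-term gain against preservation of genetic variation:

* **baseline** — truncation selection of the 100 highest-GEBV lines, random
  mating;
* **scoping** — truncation pre-selection of the top `SR` fraction of the
  population (the *scoping rate*), then sequential mate allocation: each P1
  is the best remaining candidate by GEBV and each P2 maximizes a
  marker-variance score over the growing parental set;
* **population merit** — iterative swap optimization of
  `B = g_m - c * phi`, the mean GEBV of the parental set penalized by its
  mean genomic relationship;
* **maximum variance total (MVT)** — fixed P1 half by truncation, P2 half
  optimized for the genetic-variance criterion
  `mean((1 + F_i) - 2 * Gbar_p)` within a 300-line pre-selection.

## The breeding scheme

One cycle: 50 couples each produce 20 F1, two generations of single-seed
descent (SSD) give 1000 F3 lines — the next breeding population. An RR-BLUP
model fit on a sliding training panel (TP) predicts GEBVs; the configured
strategy picks 100 parents and pairs them; the TP is updated by the *tails*
rule (the 75 highest- and 75 lowest-GEBV lines are phenotyped and replace
the 150 oldest records, so phenotyping effort is constant and the panel
stays at its initial size, 764 records for the default founder layout).
Cycle 0 is method-independent: the phenotypically best 50 lines of each
founder panel are paired across panels, so every method starts from the
same population under a shared seed.

## Genome, trait and phenotype models

Founders are fully homozygous lines over a multi-chromosome genetic map.
`L` QTL (default 100) are drawn uniformly among the loci; the remaining loci
are the prediction markers — markers are never causal. QTL effects follow a
geometric series: the k-th QTL contributes `+a^k` for the favorable
homozygote, `0` for a heterozygote and `-a^k` otherwise, with
`a = (L-1)/(L+1)`. Genetic values are reported as fractions of the maximum
`sum(a^k)`, so 1 means every favorable allele is homozygous. Effect ranks
are assigned in random order among the sampled loci, and each replicate
re-samples the whole QTL model, so replicate averages marginalize over
genetic architectures.

Meiosis uses the Haldane model: per chromosome a Poisson crossover count
with mean equal to the map length in Morgans, uniform crossover positions,
no interference, no obligate chiasma, no mutation. This is the standard
behavior of genome simulators in this field; two loci 50 cM apart therefore
recombine with frequency `(1 - exp(-1))/2 ≈ 0.316`.

Phenotypes are `y_ij = g_i + e_j + eps_ij` averaged over `n_env = 3`
environments; `e_j ~ N(0, sigma_E2)` is shared by all individuals of an
environment and `eps_ij ~ N(0, sigma_R2)` is individual-specific.
`sigma_E2` is 8 times the genetic variance of the founder population, and
`sigma_R2` is scaled once so the *entry-mean* heritability equals the target
(default 0.5): `sigma_R2 = n_env * sigma_g2 * (1 - h2)/h2`. Two choices
here were genuinely open:

* *Entry-mean vs plot-level heritability.* Selection consumes the
  environment-averaged phenotype, so we calibrate the heritability of that
  average; a plot-level definition would scale `sigma_R2` down by `n_env`.
* *Frozen calibration.* `sigma_g2` is measured once on the founders and the
  variance settings are frozen; re-calibrating per cycle would shrink the
  noise as genetic variance erodes, silently making late-cycle prediction
  easier.

## Prediction

The mixed model `y = 1*beta + Z*u + eps`, `u ~ N(0, sigma_u2 I)`,
`eps ~ N(0, sigma_e2 I)` is fit by REML on the TP after removing markers
with minor allele frequency below 0.03 (a MAF of exactly 0.03 is kept; the
filter is recomputed on the current panel before every fit and filtered
markers carry effect zero). The restricted likelihood is profiled over the
single variance ratio `delta = sigma_e2/sigma_u2` through one
eigendecomposition of the intercept-projected marker kernel `S(ZZ' + I)S`
(the `+ I` offset makes the intercept the unique null direction), then a
bracketed one-dimensional optimization over `log10(delta)` in `[-8, 8]`
with tolerance `1e-6`. This is deterministic, has no convergence failures
to handle, and costs one `n x n` eigendecomposition per cycle (n = panel
size). Marker effects come from the kernel identity
`u = Z'(ZZ' + delta I)^(-1)(y - beta)`, which the test suite checks against
the marker-dimension ridge solution.

## Optimizers and tie-breaking

The iterative strategies use deterministic best-improvement passes: each
parent slot in order is swapped with the candidate giving the largest
strict merit/criterion increase, until a full pass changes nothing (a
fixed point) or a 100-pass cap is reached (reported via a warning, never
silently). Incremental bookkeeping (running marker sums for the scoping
score; row sums of G for the relationship criteria) makes each swap
evaluation O(candidates), which the oracle tests confirm agrees with naive
recomputation to 1e-10. Everywhere, ties break by higher GEBV and then by
lower insertion index, so runs are bit-reproducible under a seed. The
scoping score uses the sample variance (denominator n - 1); a one-parent
set scores 0. "Both alleles present" at a marker is evaluated at the allele
level, so a single heterozygote suffices to clear the marker's mask bit.
The population merit's `g_m` uses mean GEBV (true values are unobservable
to a breeder), and both relationship summaries (`phi`, `Gbar_p`) average
off-diagonal entries only, since coancestry is a between-individual
quantity. Allele frequencies for the relationship matrix are recomputed
from the current breeding population each cycle.

## Synthetic founders: what they emulate and what they do not

`synth_founders()` draws per-locus allele frequencies from a uniform
spectrum on [0.05, 0.95], shared by the two panels, and samples each fully
homozygous line independently — 7 chromosomes of 150 cM by default,
mimicking the broad shape of a two-panel barley SNP dataset (764 lines,
1590 loci). It reproduces the marginal statistics that drive the method
comparison (allele-frequency spread, panel size, map density) but *not*
linkage disequilibrium structure, population stratification between real
breeding panels, or ascertainment bias of SNP arrays. Passing tests on
synthetic founders therefore demonstrate the machinery and the direction of
method differences, not the exact endpoint values a real panel would give;
with real founder files the same pipeline runs unchanged through
`read_founders()`.

## Problem sizes used by the test suite

The trajectory-level checks run the four methods on synthetic founders of
2 x 250 lines x 1590 loci for 10 replicates of 30 cycles — large enough
that the fixation-driven differences between strategies separate clearly,
small enough to run routinely on a laptop. The replicate average is over
QTL architectures and breeding stochasticity jointly; the methods share
founders and replicate seeds, so comparisons are paired. Structural counts
(1000 F1/F3, 764-record panel, 1490 markers) are checked at the full
default layout.

## Known limitations

* Additive genetics only: no dominance, epistasis, or mutation.
* No genotype-by-environment interaction; environments are balanced.
* The TP update assumes phenotyping capacity of exactly 150 lines per cycle.
* Replicates run sequentially; they are embarrassingly parallel if needed.
* Optimizers find swap-local optima, not global ones — by design, matching
  the iterative schemes they implement.

## A short run

```{r example, eval = FALSE}
founders <- synth_founders(n_lines_per_panel = 100, n_loci = 400,
                           n_chrom = 7, seed = 1)
cfg <- sim_config("scoping", SR = 0.3, n_cycles = 10, n_reps = 3,
                  master_seed = 1, founders = founders)
traj <- run_replicates(cfg)
glance(traj)    # final-cycle aggregate metrics
autoplot(traj)  # trajectories of the main metrics
```
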