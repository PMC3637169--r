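---
title: "Scoring focal and recurrent somatic alterations to rank driver genes"
author: "focalDrivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring focal and recurrent somatic alterations to rank driver genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalDrivers)
```

## The model

Tumor genomes accumulate somatic lesions — copy-number gains, deletions
and point mutations. A lesion is represented as a pair $M = (C, N)$: an
amplitude $C > 0$ (the number of copies deviated from the baseline
ploidy, or 1 for a point mutation) and the non-empty set $N$ of genes it
alters. All lesions of one type observed in one sample form a disjoint
set $S = \{M_1, \dots, M_t\}$ (`LesionSet`); overlapping same-type calls
are merged on ingest.

The premise is selectional: a sample expresses the tumor phenotype
because one of its lesions contains a driver gene. Given a prior $P^d$
over the gene universe, two posteriors for "gene $D$ is the driver given
$S$" arise from two choices of the lesion-level prior:

* **Recurrence (global) posterior** — a lesion's chance of being the
  driver lesion is proportional to the (amplitude-weighted) prior mass of
  its genes, so every altered gene competes directly:
  $$R(D \mid S) = \frac{\sum_i C_i\,\delta(D \in N_i)\,P^d(D)}
                       {\sum_i C_i \sum_{G \in N_i} P^d(G)}.$$
* **Focality (local) posterior** — every lesion has an equal
  (amplitude-weighted) chance, and its mass is then split among its own
  genes:
  $$F(D \mid S) = \sum_i \frac{C_i}{\sum_j C_j}\,
                  \frac{\delta(D \in N_i)\,P^d(D)}{\sum_{G \in N_i} P^d(G)}.$$

With a uniform prior and unit amplitudes these collapse to $1/K$ ($K$ =
altered genes in the sample) and $1/(tL)$ ($L$ = size of the gene's
lesion): recurrence treats all altered genes alike, focality rewards
genes hit by small lesions. For single-gene mutation lesions the two
coincide (each of a sample's $N$ mutated genes gets $1/N$) — note this
identity holds per sample under a *shared* prior; under a non-uniform
prior the focality value of a singleton lesion is prior-free while the
recurrence value is not, so the two *iterated* families below need not
agree, and the mutation family follows the recurrence form.

Cohort evidence is the arithmetic mean of per-sample posteriors. Two
operating depths are provided:

* `priorMode = "single_pass"`: one aggregation under the uniform prior —
  the plain "sum across samples and normalize" description.
* `priorMode = "fixed_point"` (default): the aggregation is fed back as
  the prior, $P_{j+1}(D) = \tfrac1T \sum_i P_j(D \mid S_i)$, until the
  Kullback–Leibler divergence $KL(P_{j+1} \Vert P_j)$ (in bits; this
  direction makes absolute continuity automatic, since posterior mass
  requires prior mass) falls below `tol`, or `maxIter` updates are
  reached. The update is self-reinforcing ("rich-get-richer"), which is
  exactly its point — it concentrates mass on genes that explain the
  cohort — but also why the iteration count is capped and reported in the
  run metadata rather than trusted to converge.

Gains and deletions are scored independently throughout. The combined
copy-number score is the renormalized product focality × recurrence. The
mutation score is computed on genes mutated in at least `minMutSamples`
distinct samples (default 2 — counting samples, not mutations), and
integrated scores are the renormalized product
$\text{mutation} \times (R + F)$ per copy-number type, following the
additive form in which the two copy-number scores enter the integration.

## Tiers, the entropy threshold and regions

A score distribution $P$ with entropy $H(P) = -\sum_D P(D)\log_2 P(D)$
behaves like a uniform distribution on $2^{H}$ genes. Tier round $k$
therefore declares genes with $P_k(D) > 2^{-H(P_k)}$ (strictly) to be
tier-$k$, removes them, renormalizes and repeats. Markov's inequality
makes the intuition precise: for $\varepsilon > 0$,
$\sum_{P(D) \le 2^{-(1+\varepsilon)H}} P(D) \le 1/(1+\varepsilon)$, so
the genes above the relaxed threshold always carry at least
$1 - 1/(1+\varepsilon)$ of the mass. `markovMassBound()` exposes this as
a testable property; for a zero-entropy point mass the Markov exponent
is zero and the bound is treated as vacuously true.

Two numerical choices make tiering deterministic. First, the strict
inequality means an exactly uniform remaining distribution selects
nothing; such a round (including the final single-gene round, where
$P = 1 = 2^{-0}$) parks all remaining genes in one *remainder* tier,
flagged in the output. Second, values within a relative $10^{-9}$ of the
threshold count as not exceeding it, so that an exactly uniform
remainder is not split by floating-point rounding of $2^{-H}$.

The genomic *region* construction is this package's own definition (the
underlying idea of reporting top regions with leader genes does not pin
one down): genes of tier ≤ `maxTier` are linked when at most `gapGenes`
unselected genes separate them in genome order on one chromosome;
connected runs become regions, the highest-scoring member (ties broken
by smaller start coordinate) is the leader, and regions are ranked by
leader score and truncated to `topK`. Defaults: `maxTier = 1`,
`gapGenes = 10`, `topK = 25`.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `ploidy` | 2 | autosomal baseline copies; deviation $D$ is rounded half-up, deletions capped at ploidy |
| `minOverlapFraction` | 0 | fraction of a gene's length a segment must cover; 0 = any overlap counts |
| `minMutSamples` | 2 | distinct samples for a "recurrent" mutation |
| `tol` | 1e-6 | KL stopping tolerance, bits |
| `maxIter` | 100 | cap on empirical-prior updates |
| `scoreMode` | `bayes` | `heuristic` switches to the additive $D/L$, $D/T$ per-gene sums normalized once at the end |
| `maxTier`, `gapGenes`, `topK` | 1, 10, 25 | region construction |

Further fixed numerical conventions: score vectors must sum to 1 within
$10^{-9}$ (the all-zero "empty" vector of an unscorable sample is
excluded from aggregation); internal coordinates are 0-based half-open
with every reader converting on ingest (SEG 1-based inclusive, BED
0-based half-open, refFlat 1-based start); duplicate gene symbols merge
to their union span on one chromosome and are dropped across
chromosomes; overlapping same-type lesion calls merge with gene-set
union and *maximum* amplitude (overlapping calls usually re-describe one
event; summing would double-count); non-autosomes are excluded from the
gene model by default.

## What the synthetic generator emulates

`simulateCohort()` draws from a deliberately plain generative model: a
regular genome (evenly spaced, equal-length genes on equal chromosomes);
Poisson-many passenger copy-number lesions per sample, uniformly placed,
geometric sizes, amplitudes 1 or 2 (weights 0.7/0.3); implanted drivers
hit independently per sample with probability `hitProb` by focal lesions
(geometric size, mean 3 genes) of the driver's type; Bernoulli
per-gene passenger mutations and elevated per-driver mutation rates. The
geometric size law was chosen as the simplest one-parameter
heavier-tailed distribution on positive counts; nothing is claimed about
its realism.

The default configuration — 2,000 genes on 8 chromosomes, 50 samples, 5
drivers (3 gain, 2 deletion) at `hitProb` 0.4, 10 passenger lesions per
sample of mean size 50 genes, passenger mutation rate 0.002 per gene per
sample, driver mutation rate 0.15, seed 20130325 — is the package's
standard recovery scenario: the headline functional test requires all 5
implanted drivers in the integrated-score top 10 (each driver judged in
its own type's integrated table), and a matched negative control with no
implanted signal to recover at most 1 of 5 randomly designated genes.
These problem sizes are also what `scripts/acceptance.R` re-runs.

What the generator does *not* emulate — chromosome-arm structure, fragile
sites and recurrent passenger hotspots, GC/wave artifacts, subclonality
and purity, two-hit dynamics, mutation-class structure — bounds what
passing tests show: they validate the inference machinery (the
posteriors, the fixed point, tiering, region logic and the full I/O loop)
under honest noise, not performance on real tumor cohorts, where
hotspot passengers and correlated lesions can mimic drivers.

## Open design choices made here

* The Bayesian posteriors are canonical; the additive heuristic is kept
  as a compatibility mode (`scoreMode = "heuristic"`), since the two
  differ by a per-sample normalization and published rankings could rest
  on either.
* The default report is the converged fixed point;
  `priorMode = "single_pass"` reproduces the one-step description. Each
  score family (recurrence/focality × gain/deletion, mutation) is
  iterated independently with its own trace.
* The mutation family is iterated with the recurrence posterior, the form
  the mutation score is defined by analogy with.
* Integration uses the *sum* $R + F$ of the copy-number scores (not the
  combined product), matching the stated integration formula.
* The gene model is a free input: no particular annotation or gene count
  is assumed.
* `iterateEmpiricalPrior()` runs on a vectorized index representation of
  the cohort; a dual-route test holds it to $10^{-12}$ agreement, at
  every iteration depth, with explicitly aggregating the public
  per-sample posterior functions.

## Known limitations

Scores are relative evidence, not calibrated significance — no q-values
are produced, and no correction is attempted for gene length, local
background alteration rate, purity or ploidy estimation error. Activating
and inactivating mutations are not distinguished. Samples present in only
one data type simply contribute nothing to the other (no imputation).
Non-convergence within `maxIter` leaves a warning and the last iterate,
which on diffuse cohorts can still be a useful ranking but should be read
alongside the reported final KL step.

## Session info

```{r}
sessionInfo()
```
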