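---
title: "Estimating mutational bias and a GC-favoring force at short intronic sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutational bias and a GC-favoring force at short intronic sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sispec)
library(dplyr)
```

## The scientific problem

Positions 8–30 bp from the 5' end of Drosophila introns shorter than 66 bp
("SI sites") are widely used as a neutral reference class: they show the
highest divergence and diversity in the genome and little evidence of
selective constraint. If they are truly neutral, their base composition is
shaped only by mutation and drift — plus any *non-selective* directional
force such as GC-biased gene conversion (gBGC), which transmits G/C
("strong", S) alleles preferentially over A/T ("weak", W) alleles during
recombination-associated repair and behaves exactly like semidominant
selection of scaled strength $\gamma = 4 N_e s$.

`sispec` implements both sides of the inference:

* **Polymorphism.** Class-specific unfolded site frequency spectra (SFSs)
  for S>W, W>S, and neutral (W>W / S>S) segregating mutations, polarized
  with two outgroups, are fitted with a Poisson likelihood whose
  parameters are the force $\gamma$, class mutation inputs $\theta_c$,
  demographic distortion multipliers $r_j$, and optionally
  polarization-error probabilities $\varepsilon$. The mutational bias
  $\kappa = u/v$ (S$\to$W over W$\to$S per-site rate) is a derived
  quantity, $\kappa = (\theta_{SW}/L_S)/(\theta_{WS}/L_W)$.
* **Divergence.** A nonstationary three-taxon substitution model with
  per-branch target compositions is fitted to alignment columns; expected
  numbers of labelled substitutions per lineage are obtained by expected
  Markov counting, integrating over ancestral states rather than fixing a
  single reconstruction. The per-site rate ratio
  $R = r_{S>W} / r_{W>S}$ equals $\kappa$ under strict neutrality and
  $\kappa e^{-\gamma}$ under a semidominant force.
* **Equilibrium algebra.** The closed forms linking these quantities:
  equilibrium GC $= 1/(1+\kappa e^{-\gamma})$, its inversions in
  $\gamma$ and $\kappa$, and $R = \kappa e^{-\gamma}$.

## The SFS model

For a mutation with semidominant scaled coefficient $\gamma$, the
expected unfolded spectrum in a sample of $n$ haploid genomes is

$$E[\xi_j] = \theta \binom{n}{j} \int_0^1
\frac{1 - e^{-\gamma(1-x)}}{(1 - e^{-\gamma})\,x(1-x)}
x^j (1-x)^{n-j}\,dx,$$

the classical diffusion sojourn density sampled binomially; at
$\gamma = 0$ this is the neutral law $\theta/j$. The W>S class uses
$+\gamma$, S>W uses $-\gamma$, and the neutral class the
$\gamma \to 0$ limit. Observed cells are independent Poisson draws around
$r_j \, E[\xi_j]$, where the distortions $r_j$ ($r_1 \equiv 1$ for
identifiability, shared across classes) absorb demographic departures
from the standard neutral shape — the device that lets the method avoid
assuming demographic equilibrium. Models are nested: `M0`
($\gamma = 0$), `M1` ($\gamma$ free), and `M0*`/`M1*`, which model each
observed cell as a mixture $(1-\varepsilon)$ of its own class with
$\varepsilon$ of the frequency-reflected opposite class (neutral is its
own opposite), absorbing residual mis-polarization.

Numerical choices: the integrand is smooth on $(0,1)$ for $j \ge 1$
(the endpoint singularities cancel against the binomial kernel), so a
fixed 64-point Gauss–Legendre rule evaluates it to near machine
precision (verified against adaptive quadrature at $10^{-9}$ relative).
$|\gamma|$ is capped at 50 to avoid overflow. For `M0`/`M1` the
$\theta_c$ and $r_j$ have closed-form conditional Poisson MLEs, so the
likelihood is profiled exactly inside a one-dimensional search over
$\gamma$ (coarse grid plus local refinement; restarts jitter the grid).
The $\gamma = 0$ profile is always a candidate for `M1`, so
`loglik(M1) >= loglik(M0)` holds by construction. Starred models lose
the closed-form profiling and use BFGS over log/logit-transformed
parameters initialized from the non-star fit.

```{r fit-example}
sfs <- simulate_class_sfs(sim_config(gamma = 2, kappa = 3, seed = 1))
fit <- fit_sfs_model(sfs, "M1", seed = 1)
glance(fit)
```

## Polarization

Ancestral alleles are inferred probabilistically from two outgroups on
the fixed topology ((ingroup, outgroup1), outgroup2) under the Kimura
2-parameter model (a 6-parameter model adds nothing detectable for these
species distances). Each site's likelihood sums over the ingroup-ancestor
state, weighted by a derived-allele-count prior that is refined by a few
EM passes (posterior count frequencies re-enter as the prior). The
spectra are built with probability weighting: a segregating site
contributes $p$ to one orientation at derived count $j$ and $1-p$ to the
opposite orientation at $n-j$, conserving segregating-site mass exactly.
Hard rounding is available (`round_counts = TRUE`) but not the default,
since the starred models downstream are the principled treatment of
residual misorientation.

## Divergence

The three-taxon tree is rooted at the ingroup/sister common ancestor,
whose composition is a free parameter; each branch has its own target
composition (nonstationary) with shared symmetric exchangeabilities.
Branch length is calibrated as expected substitutions per site at the
branch's own target composition. A stationary GTR fitted to the same
columns provides the likelihood-ratio comparison (9 d.f.). Expected
labelled counts use the eigendecomposition closed form for
$E[N_{i \to j} \mid X_0 = a, X_t = b]$ (complex-safe, since
composition-targeted chains need not be reversible), with a uniformized
Simpson quadrature fallback for defective eigenbases. Ancestral site
totals $L_{GC}$, $L_{AT}$ are posterior expectations over the root
state.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions: 9327 introns of 23 bp SI sites (~214 kb), haploid samples of
$n = 21$ or 69, mutational bias $\kappa = 3$, no force
($\gamma = 0$) so target GC is the mutational equilibrium 0.25, class
mutation inputs of 4000 (tens of thousands of segregating sites, the
scale of the empirical data), branch lengths 0.058/0.066 for the two
ingroup lineages and 0.25 for the outgroup, no distortion and no
polarization error. SFS cells are Poisson (not multinomial), matching
the likelihood. The triplet simulator draws a root sequence per intron
and evolves each branch by exact Gillespie simulation of a
composition-targeted chain, recording true labelled substitution
counts; a polymorphism overlay then *replaces* fixed states at the
chosen sites (a site is polymorphic or fixed, never both, avoiding
double counting). In pipeline runs the S>W mutation input is scaled by
$\kappa \cdot g/(1-g)$ for bin GC $g$, so the planted $\kappa$ is
consistent with the simulated composition.

What the generator does *not* emulate: linkage and hitchhiking,
recombination-rate variation, indels, context-dependent mutation,
alignment error, and base-calling error. Passing tests therefore
demonstrate correctness of the inference machinery under the model's own
assumptions, not robustness to every property of real data.

An independent forward Wright–Fisher oracle validates the diffusion
expectation: haploid population of size $M$, per-copy advantage
$\sigma = \gamma/(2M)$, sojourn counting of injected mutations, and
hypergeometric subsampling, which reproduces `expected_sfs()` within
Monte-Carlo error for $\gamma \in \{-2, 0, 2\}$.

## Bootstrap and binning

Introns (never sites) are the resampling unit: percentile CIs from 1000
resamples by default, with undefined replicates skipped and counted
(more than 10% is an error). GC quintiles use a stable sort with ties
broken by intron id, and the remainder appended to the final bin — the
convention that reproduces the 1865/1865/1865/1865/1867 partition of
9327 introns exactly.

## Equilibrium diversity

For two parameter pairs, `predict_relative_diversity()` evaluates the
low-mutation equilibrium heterozygosity
$H(\kappa, \gamma) \propto 2\kappa(e^\gamma - 1) / (\gamma(\kappa + e^\gamma))$,
derived from the equilibrium W/S site fractions and the sojourn
heterozygosity of favored and disfavored mutations. The internal ground
truth is numeric integration over Wright's stationary density with the
endpoint singularities removed by power substitutions; closed form and
integral agree to three significant figures across the tested
$(\kappa, \gamma)$ grid. One subtlety the tests document: with biased
mutation ($\kappa > 1$), a *weak* GC-favoring force first rebalances
composition and raises diversity; strict monotone decay in $|\gamma|$
holds for symmetric mutation or beyond the rebalancing region.

## Pipeline and problem sizes

`run_pipeline()` executes simulate (or extract/intersect/filter/bin on
real annotation inputs) → polarize → diversity/DAF → model fits and
LRTs → divergence counting per bin, writing TSV tables, a JSON summary,
a structured log with per-filter attrition counts, and optional figures.
All randomness derives from one master seed split per stage and bin;
identical configurations give byte-identical JSON.

The test suite exercises the chain at reduced but non-trivial sizes —
300–3000 introns per dataset, 12 replicates per cell of the
$3 \times 3$ parameter-recovery grid, 200 replicates for the
likelihood-ratio calibration, $10^5$ paths for the counting oracle —
sizes at which estimator noise is small enough for the planted-gradient
and bias checks to be sharp while the whole suite runs in minutes.

## Known limitations

* The polarization prior is an EM-refined empirical spectrum, not a
  joint MLE over prior and branch parameters; with very few sites the
  prior is noisy (the model fits are the downstream correction).
* Branch lengths are normalized at each branch's target composition;
  when composition is far from target, realized substitutions per site
  differ from the nominal length (expected counts, which are what the
  analyses use, are unaffected).
* The X chromosome is out of scope (the empirical datasets carry too few
  X-linked SNPs to bin), as are read mapping, variant calling, and
  whole-genome alignment construction.
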