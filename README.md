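# sispec

Mutational bias and GC-favoring fixation forces at short intronic sites.

## What this package is for

Short introns in *Drosophila* — specifically positions 8–30 bp from the
5' end of introns shorter than 66 bp ("SI sites") — are a standard
neutral reference class in population genetics. If they are truly free
of selection, their base composition is governed by the mutational bias
**κ = u/v** (the GC→AT over AT→GC per-site mutation rate ratio) and any
non-selective directional force such as **GC-biased gene conversion
(gBGC)**, which favors G/C ("strong", S) over A/T ("weak", W) alleles
with an evolutionary effect identical to semidominant selection of
scaled strength **γ = 4·Nₑ·s**.

`sispec` is for population geneticists who want to estimate (γ, κ) at
putatively neutral sites from two independent signals:

* **Polymorphism** — class-specific unfolded site frequency spectra
  (S>W, W>S, neutral changes) polarized with two outgroups, fitted by an
  independent-Poisson likelihood with expected cells

  E[ξⱼ] = θ·C(n,j)·∫₀¹ [(1 − e^(−γ(1−x))) / ((1 − e^(−γ))·x(1−x))] ·
  xʲ(1−x)^(n−j) dx,

  nuisance distortion multipliers rⱼ for demography, and optional
  polarization-error mixing (models M0/M0\*/M1/M1\* compared by
  likelihood-ratio tests). κ is derived as
  (θ_SW/L_S)/(θ_WS/L_W).
* **Divergence** — a nonstationary three-taxon substitution model with
  branch-specific base compositions, and expected Markov counting of
  labelled substitutions per lineage, giving per-site rates
  r_S>W = N_S>W/L_GC, r_W>S = N_W>S/L_AT and their ratio
  **R = r_S>W/r_W>S**, which equals κ under neutrality and κ·e^(−γ)
  under a semidominant force.

The closed-form equilibrium algebra ties the two together:
equilibrium GC = 1/(1 + κ·e^(−γ)), with analytic inversions in γ and κ.

A first-class synthetic-data module (`sim_config()`,
`simulate_class_sfs()`, `simulate_triplet_alignment()`,
`wright_fisher_oracle()`) generates inputs with known ground truth at
the scale of the empirical study (9327 introns × 23 bp, n = 21 or 69
haploid genomes, two outgroup lineages), so the entire chain is testable
without any external download. Annotation utilities
(`extract_short_introns()`, `intersect_homologous_sites()`,
`apply_site_filters()`, `assign_gc_bins()`, `bootstrap_ci()`) implement
the SI-site definition, homologous-site intersection via
whole-genome-alignment columns, the site filters, GC quintile binning,
and intron-level bootstrap CIs for real GFF3/FASTA/WGA-BED inputs.

## Worked example

Simulate a population with a planted GC-favoring force and recover it:

```r
library(sispec)

sfs <- simulate_class_sfs(sim_config(gamma = 1.5, kappa = 3, n = 21, seed = 42))
sfs
#> Class-specific unfolded SFS: n = 21, 43114.0 segregating sites
#>   S>W 11734.0 | W>S 16962.0 | neutral 14418.0 | L_W 160890.8 | L_S 53630.25

fit <- fit_sfs_model(sfs, "M1", seed = 1)
glance(fit)
#> # A tibble: 1 x 7
#>   model     n gamma kappa loglik    np convergence
#>   <chr> <int> <dbl> <dbl>  <dbl> <int>       <int>
#> 1 M1       21  1.44  2.97  -255.    23           0

likelihood_ratio_test(fit_sfs_model(sfs, "M0"), fit)
#> # A tibble: 1 x 3
#>   statistic    df   p_value
#>       <dbl> <int>     <dbl>
#> 1      795.     1 5.69e-175
```

The fit recovers the planted parameters (γ̂ = 1.44 vs 1.5,
κ̂ = 2.97 vs 3; the spread of γ̂ at this θ is about ±0.05 across
seeds), and the M0-vs-M1 test overwhelmingly rejects γ = 0. The W>S
spectrum carries more sites at higher frequencies than S>W — the
polymorphism signature of a GC-favoring force. Closed-form
interpretation of such a fit:

```r
gc_equilibrium(kappa = 3, gamma = 0)            # 0.25  (neutral equilibrium GC)
substitution_ratio_R(kappa = 2.8, gamma = -0.35) # 3.97 (implied rate ratio)
required_kappa(gc = 0.195)                      # 4.13 (bias needed under neutrality)
equilibrium_chi2(3500, 3584)                    # chi2 = 1.0, p = 0.32 (1:1 test)
```

`run_pipeline(pipeline_config(...))` drives the full per-bin analysis
(simulate or extract → polarize → diversity/DAF → model fits → divergence)
and writes TSV tables, a JSON summary, and a structured log; see the
vignette in `vignettes/gbgc-short-introns.Rmd` for the model details and
design choices.

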