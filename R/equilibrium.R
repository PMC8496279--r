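#' Equilibrium GC content under mutation bias and a GC-favoring force
#'
#' At mutation-fixation equilibrium for a biallelic weak/strong (AT/GC)
#' system with mutational bias `kappa = u/v` (the GC-to-AT over AT-to-GC
#' mutation rate ratio) and a semidominant directional force of scaled
#' strength `gamma = 4*Ne*s` favoring GC, the expected equilibrium GC
#' fraction is `1 / (1 + kappa * exp(-gamma))`.  With `gamma = 0` this
#' reduces to the purely mutational equilibrium `1 / (1 + kappa)`.
#'
#' @param kappa Mutational bias `u/v` (GC-to-AT rate over AT-to-GC rate);
#'   must be positive.
#' @param gamma Scaled strength of the force favoring GC (dimensionless).
#' @return Equilibrium GC fraction in (0, 1).
#' @examples
#' gc_equilibrium(kappa = 3, gamma = 0) # 0.25
#' @export
gc_equilibrium <- function(kappa, gamma) {
  check_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_number(gamma, "gamma")
  1 / (1 + kappa * exp(-gamma))
}

#' Force strength required for a given equilibrium GC content
#'
#' Analytic inverse of [gc_equilibrium()] in `gamma`:
#' `gamma = -log((1 - gc) / (gc * kappa))`.
#'
#' @param gc Equilibrium GC fraction, strictly inside (0, 1).
#' @inheritParams gc_equilibrium
#' @return The scaled force `gamma` producing equilibrium GC `gc` under
#'   mutational bias `kappa`.
#' @examples
#' solve_gamma_for_gc(gc = 0.20, kappa = 2.8) # about -0.35
#' @export
solve_gamma_for_gc <- function(gc, kappa) {
  check_number(gc, "gc", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  -log((1 - gc) / (gc * kappa))
}

#' Substitution-rate ratio implied by kappa and gamma
#'
#' The ratio of per-site substitution rates `R = r_SW / r_WS` (GC-to-AT over
#' AT-to-GC) implied by mutational bias `kappa` and a semidominant fixation
#' force `gamma` favoring GC is `R = kappa * exp(-gamma)`: the ratio of the
#' two mutation rates times the ratio of fixation probabilities of
#' disfavored (-gamma) to favored (+gamma) semidominant mutations.  Under
#' strict neutrality (`gamma = 0`), `R = kappa`.
#'
#' @inheritParams gc_equilibrium
#' @return The implied substitution-rate ratio (positive number).
#' @examples
#' substitution_ratio_R(kappa = 2.8, gamma = -0.35) # about 3.97
#' @export
substitution_ratio_R <- function(kappa, gamma) {
  check_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_number(gamma, "gamma")
  kappa * exp(-gamma)
}

#' Mutational bias required for a neutral equilibrium GC content
#'
#' Neutral inversion of [gc_equilibrium()] in `kappa`:
#' `kappa = (1 - gc) / gc`.
#'
#' @inheritParams solve_gamma_for_gc
#' @return The mutational bias `kappa` for which `gc` is the neutral
#'   (`gamma = 0`) equilibrium.
#' @examples
#' required_kappa(0.195) # about 4.13
#' @export
required_kappa <- function(gc) {
  check_number(gc, "gc", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  (1 - gc) / gc
}

#' Pearson chi-squared test for equal W>S and S>W substitution counts
#'
#' At base-composition equilibrium the numbers of weak-to-strong and
#' strong-to-weak substitutions along a lineage are expected to be equal.
#' This tests the observed pair of counts against a 1:1 expectation with the
#' standard Pearson statistic (no continuity correction), df = 1.
#'
#' @param n_ws Observed number of W>S (AT-to-GC) substitutions.
#' @param n_sw Observed number of S>W (GC-to-AT) substitutions.
#' @return A one-row tibble with `statistic`, `df`, and `p_value`.
#' @examples
#' equilibrium_chi2(3500, 3584)
#' @export
equilibrium_chi2 <- function(n_ws, n_sw) {
  check_number(n_ws, "n_ws", lower = 0)
  check_number(n_sw, "n_sw", lower = 0)
  if (n_ws + n_sw <= 0) abort("Both substitution counts are zero.")
  expected <- (n_ws + n_sw) / 2
  stat <- (n_ws - expected)^2 / expected + (n_sw - expected)^2 / expected
  tibble(
    statistic = stat,
    df = 1L,
    p_value = pchisq(stat, df = 1L, lower.tail = FALSE)
  )
}

#' Expected new mutations per haploid genome per generation
#'
#' Convenience product `mu * genome_size`, e.g. a per-base rate of 5e-9 over
#' a 1.4e8 bp genome gives 0.7 new mutations per haploid genome per
#' generation.
#'
#' @param mu Per-base-pair mutation rate per generation.
#' @param genome_size Haploid genome size in base pairs.
#' @return Expected number of new mutations per haploid genome per
#'   generation.
#' @export
mutations_per_generation <- function(mu, genome_size) {
  check_number(mu, "mu", lower = 0)
  check_number(genome_size, "genome_size", lower = 0)
  mu * genome_size
}
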