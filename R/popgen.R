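# Standard diversity summaries, singleton diagnostics, per-class derived
# allele frequencies, and the equilibrium diversity predictor.

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Diversity and singleton summaries for a set of polymorphic sites
#'
#' Computes per-site nucleotide diversity `pi` (average pairwise
#' difference), Watterson's `theta_w = S / (a_n * L)` with
#' `a_n = sum_{i=1}^{n-1} 1/i`, Tajima's D with the standard
#' normalization, the proportion of segregating sites that are derived
#' (unfolded) singletons, and that proportion divided by its neutral
#' equilibrium expectation `1 / a_n`.
#'
#' @param data Tibble of segregating sites with a column of derived-allele
#'   counts named `j` (values in `1..n-1`).
#' @param n Haploid sample size (>= 2).
#' @param total_sites Total number of surveyed sites `L` (monomorphic plus
#'   segregating), the denominator of the per-site rates.
#' @return A one-row tibble: `pi`, `theta_w`, `tajima_d`,
#'   `prop_singletons`, `singleton_ratio`, `S`, `n`, `total_sites`.
#' @export
diversity_summary <- function(data, n, total_sites) {
  n <- as.integer(n)
  if (n < 2L) abort("`n` must be at least 2.")
  check_number(total_sites, "total_sites", lower = 1)
  j <- data$j
  if (length(j) > 0 && (any(j < 1) || any(j > n - 1))) {
    abort("Derived counts must lie in 1..n-1.")
  }
  S <- length(j)
  k <- tajima_constants(n)
  pi_total <- sum(2 * j * (n - j) / (n * (n - 1)))
  theta_w_total <- S / k$a1
  tajima_d <- if (S > 0) {
    (pi_total - theta_w_total) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  } else {
    NA_real_
  }
  prop_singletons <- if (S > 0) sum(j == 1) / S else NA_real_
  tibble(
    pi = pi_total / total_sites,
    theta_w = theta_w_total / total_sites,
    tajima_d = tajima_d,
    prop_singletons = prop_singletons,
    singleton_ratio = prop_singletons * k$a1,
    S = S, n = n, total_sites = total_sites
  )
}

#' Mean derived allele frequency per mutation class
#'
#' For each class `c`, `DAF_c = sum_j j * xi_c[j] / (n * sum_j xi_c[j])`.
#' An elevated `DAF_WS` relative to `DAF_SW` is the polymorphism signature
#' of a force favoring strong (G/C) alleles.
#'
#' @param sfs A [class_sfs()].
#' @return A tibble with one row per class: `class`, `daf`, and the class
#'   total `segregating`.
#' @export
mean_daf <- function(sfs) {
  stopifnot(inherits(sfs, "class_sfs"))
  j <- seq_len(sfs$n - 1L)
  purrr::map_dfr(SFS_CLASSES, function(cl) {
    tot <- sum(sfs$xi[cl, ])
    tibble(
      class = cl,
      daf = if (tot > 0) sum(j * sfs$xi[cl, ]) / (sfs$n * tot) else NA_real_,
      segregating = tot
    )
  })
}

#' Equilibrium heterozygosity under mutation, drift, and a directional force
#'
#' Expected nucleotide diversity per unit of W-to-S mutation input at
#' mutation-selection-drift equilibrium in the low-mutation limit,
#' for mutational bias `kappa` and semidominant force `gamma`:
#' `H(kappa, gamma) = 2 * kappa * (exp(gamma) - 1) / (gamma * (kappa + exp(gamma)))`
#' (with the continuous limit `2 * kappa / (kappa + 1)` at `gamma = 0`).
#' This combines the equilibrium fractions of AT- and GC-fixed sites with
#' the sojourn heterozygosity of favored and disfavored mutations.
#'
#' @inheritParams gc_equilibrium
#' @return Expected equilibrium heterozygosity per unit mutation input.
#' @seealso [predict_relative_diversity()] and
#'   [equilibrium_diversity_wright()], the numeric-integration check over
#'   Wright's stationary density.
#' @export
equilibrium_diversity <- function(kappa, gamma) {
  check_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_number(gamma, "gamma")
  if (abs(gamma) < 1e-9) {
    2 * kappa / (kappa + 1)
  } else {
    2 * kappa * expm1(gamma) / (gamma * (kappa + exp(gamma)))
  }
}

#' Numeric equilibrium heterozygosity from Wright's stationary density
#'
#' Ground-truth check of [equilibrium_diversity()]: integrates
#' `2x(1-x)` against Wright's stationary allele-frequency density
#' `phi(x) = exp(gamma * x) * x^(theta - 1) * (1 - x)^(kappa * theta - 1)`
#' (x = frequency of the strong allele; mutation input to S is `theta`,
#' to W is `kappa * theta`), normalized over the same density.  The
#' integrable endpoint singularities are removed by the substitutions
#' `t = x^theta` and `s = (1-x)^(kappa * theta)`.  As `theta -> 0` the
#' result divided by `theta` converges to the closed form.
#'
#' @inheritParams gc_equilibrium
#' @param theta Scaled per-site mutation rate toward S (small; default
#'   1e-4).
#' @return Mean heterozygosity `E[2x(1-x)]`, per unit theta.
#' @export
equilibrium_diversity_wright <- function(kappa, gamma, theta = 1e-4) {
  check_number(theta, "theta", lower = 0, strict_lower = TRUE)
  bS <- theta
  bW <- kappa * theta
  core <- function(x) exp(gamma * x) * x^(bS - 1) * (1 - x)^(bW - 1)
  # denominator: substitutions remove the x^(bS-1) and (1-x)^(bW-1) spikes
  lower_half <- stats::integrate(
    function(t) {
      x <- t^(1 / bS)
      exp(gamma * x) * (1 - x)^(bW - 1) / bS
    }, 0, 0.5^bS, rel.tol = 1e-10
  )$value
  upper_half <- stats::integrate(
    function(s) {
      x <- 1 - s^(1 / bW)
      exp(gamma * x) * x^(bS - 1) / bW
    }, 0, 0.5^bW, rel.tol = 1e-10
  )$value
  numer <- stats::integrate(
    function(x) 2 * x * (1 - x) * core(x), 0, 1, rel.tol = 1e-10
  )$value
  numer / ((lower_half + upper_half) * theta)
}

#' Predicted ratio of equilibrium diversities for two parameter pairs
#'
#' Evaluates [equilibrium_diversity()] for two `(kappa, gamma)` pairs and
#' returns the ratio `a / b`: the expected relative nucleotide diversity
#' of two site classes if both sit at mutation-selection-drift equilibrium
#' with the same underlying mutation rate and effective population size.
#'
#' @param fit_a,fit_b Either `gbgc_fit` objects or lists/vectors with
#'   elements `kappa` and `gamma`.
#' @return The predicted diversity ratio (scalar).
#' @export
predict_relative_diversity <- function(fit_a, fit_b) {
  get_kg <- function(f) {
    if (inherits(f, "gbgc_fit")) c(kappa = f$kappa, gamma = f$gamma)
    else c(kappa = f[["kappa"]], gamma = f[["gamma"]])
  }
  a <- get_kg(fit_a)
  b <- get_kg(fit_b)
  equilibrium_diversity(a[["kappa"]], a[["gamma"]]) /
    equilibrium_diversity(b[["kappa"]], b[["gamma"]])
}
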