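# Two-outgroup probabilistic inference of the ancestral allele under the
# Kimura 2-parameter model, in the style of est-sfs: the likelihood of each
# site's configuration is summed over the state of the ingroup ancestor
# and of the internal node joining it to the first outgroup, weighted by a
# derived-allele-frequency prior that is itself refined by EM.

TRANSITION_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")

# K2P transition probability matrix for a branch with transition amount
# `a` (= alpha * t) and per-target transversion amount `b` (= beta * t).
k2p_matrix <- function(a, b) {
  p_same <- 0.25 + 0.25 * exp(-4 * b) + 0.5 * exp(-2 * (a + b))
  p_ts <- 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b))
  p_tv <- 0.25 - 0.25 * exp(-4 * b)
  P <- matrix(p_tv, 4, 4, dimnames = list(BASES, BASES))
  diag(P) <- p_same
  for (x in BASES) P[x, TRANSITION_PARTNER[[x]]] <- p_ts
  P
}

# T[z, o1, o2]: probability of (o1, o2) and ingroup-ancestor z, summing
# over the internal node state with the uniform K2P stationary root.
k2p_triplet_array <- function(par) {
  P1 <- k2p_matrix(par[1], par[2]) # ingroup ancestor -- node
  P2 <- k2p_matrix(par[3], par[4]) # outgroup 1 -- node
  P3 <- k2p_matrix(par[5], par[6]) # outgroup 2 -- node (root folded in)
  T_arr <- array(0, c(4, 4, 4), dimnames = list(BASES, BASES, BASES))
  for (y in 1:4) {
    T_arr <- T_arr + 0.25 * outer(P1[y, ], outer(P2[y, ], P3[y, ]))
  }
  T_arr
}

# Collapse a site table into weighted patterns.  Patterns are keyed by
# (major, minor, major_count, o1, o2); minor is "" for monomorphic sites.
collapse_site_patterns <- function(sites, n) {
  stopifnot(all(c("major", "minor", "major_count", "o1", "o2") %in%
                  names(sites)))
  if (any(sites$major_count + dplyr::coalesce(sites$minor_count, 0L) != n)) {
    abort("Every site must have a complete ingroup sample of size n.")
  }
  sites |>
    mutate(minor = dplyr::coalesce(.data$minor, "")) |>
    dplyr::count(.data$major, .data$minor, .data$major_count,
                 .data$o1, .data$o2, name = "count")
}

# Site-pattern likelihood components: for each pattern, the weighted terms
# for each candidate ingroup-ancestor state.
pattern_terms <- function(pat, T_arr, g, n) {
  io1 <- match(pat$o1, BASES)
  io2 <- match(pat$o2, BASES)
  im <- match(pat$major, BASES)
  imin <- match(pat$minor, BASES) # NA for monomorphic
  seg <- !is.na(imin)
  # weight of ancestor = major: derived is minor at count n - major_count
  # (monomorphic sites have derived count 0)
  w_major <- g[ifelse(seg, n - pat$major_count, 0L) + 1L]
  lik_major <- T_arr[cbind(im, io1, io2)] * w_major
  lik_minor <- rep(0, nrow(pat))
  lik_minor[seg] <- T_arr[cbind(imin[seg], io1[seg], io2[seg])] *
    g[pat$major_count[seg] + 1L]
  # monomorphic sites can also descend from any other ancestor with all n
  # copies derived
  lik_other <- rep(0, nrow(pat))
  if (any(!seg)) {
    for (z in 1:4) {
      zpat <- !seg & im != z
      lik_other[zpat] <- lik_other[zpat] +
        T_arr[cbind(rep(z, sum(zpat)), io1[zpat], io2[zpat])] * g[n + 1L]
    }
  }
  list(major = lik_major, minor = lik_minor, other = lik_other,
       total = lik_major + lik_minor + lik_other)
}

#' Fit the two-outgroup K2P polarization model
#'
#' Maximum-likelihood fit of Kimura 2-parameter branch parameters on the
#' fixed topology ((ingroup, outgroup1), outgroup2), where each site's
#' likelihood sums over the ingroup-ancestor state weighted by a
#' derived-allele-count prior.  The prior is initialized as a
#' neutral-shaped spectrum and refined by a small number of EM passes
#' (posterior count frequencies re-enter as the new prior).  The branch
#' optimization is repeated from `n_restarts` jittered starts; the vector
#' of per-start best log-likelihoods is kept as a convergence diagnostic.
#'
#' @param sites Tibble with columns `major`, `minor` (`NA` when
#'   monomorphic), `major_count`, `minor_count`, `o1`, `o2`; see
#'   [triplet_sites()].
#' @param n Haploid ingroup sample size.
#' @param n_restarts Number of jittered optimization starts (default 10).
#' @param seed Integer seed for the jitter.
#' @param em_iter Number of prior-refinement passes (default 3).
#' @return An `outgroup_model`: per-branch transition/transversion
#'   amounts, the fitted derived-count prior, the log-likelihood, and the
#'   per-start log-likelihoods.
#' @export
fit_outgroup_model <- function(sites, n, n_restarts = 10L, seed = NULL,
                               em_iter = 3L) {
  if (!is.null(seed)) set.seed(seed)
  pat <- collapse_site_patterns(sites, n)
  # neutral-shaped initial prior over derived counts 0..n
  g <- c(0.7, 0.28 * (1 / seq_len(n - 1L)) / sum(1 / seq_len(n - 1L)), 0.02)

  negll <- function(logpar, prior) {
    T_arr <- k2p_triplet_array(exp(logpar))
    tt <- pattern_terms(pat, T_arr, prior, n)
    ll <- sum(pat$count * log(pmax(tt$total, 1e-300)))
    if (!is.finite(ll)) 1e12 else -ll
  }

  best <- NULL
  lls <- numeric(0)
  for (it in seq_len(max(1L, em_iter))) {
    starts <- if (it == 1L) max(1L, n_restarts) else 2L
    round_best <- NULL
    for (k in seq_len(starts)) {
      init <- if (!is.null(best)) {
        best$par + rnorm(6, 0, if (k == 1L) 0 else 0.3)
      } else {
        log(c(0.05, 0.05, 0.1, 0.1, 0.2, 0.2)) +
          rnorm(6, 0, if (k == 1L) 0 else 0.5)
      }
      o <- tryCatch(
        optim(init, negll, prior = g, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (is.null(o)) next
      if (it == 1L) lls <- c(lls, -o$value)
      if (is.null(round_best) || o$value < round_best$value) round_best <- o
    }
    if (is.null(round_best)) abort("All optimization starts failed.")
    best <- round_best
    # EM pass: update the derived-count prior from pattern posteriors
    T_arr <- k2p_triplet_array(exp(best$par))
    tt <- pattern_terms(pat, T_arr, g, n)
    g_new <- numeric(n + 1L)
    seg <- pat$minor != ""
    d_major <- ifelse(seg, n - pat$major_count, 0L) # z = major
    d_minor <- pat$major_count                      # z = minor
    post_major <- pat$count * tt$major / tt$total
    post_minor <- pat$count * tt$minor / tt$total
    post_other <- pat$count * tt$other / tt$total
    for (i in seq_len(nrow(pat))) {
      g_new[d_major[i] + 1L] <- g_new[d_major[i] + 1L] + post_major[i]
      if (seg[i]) {
        g_new[d_minor[i] + 1L] <- g_new[d_minor[i] + 1L] + post_minor[i]
      }
    }
    g_new[n + 1L] <- g_new[n + 1L] + sum(post_other)
    g <- pmax(g_new / sum(g_new), 1e-8)
  }

  structure(
    list(
      branch_params = matrix(exp(best$par), nrow = 3L, byrow = TRUE,
                             dimnames = list(c("ingroup", "outgroup1",
                                               "outgroup2"),
                                             c("transition", "transversion"))),
      prior = g, n = n, loglik = -best$value,
      restart_logliks = lls, convergence = best$convergence
    ),
    class = "outgroup_model"
  )
}

#' @export
print.outgroup_model <- function(x, ...) {
  cat(sprintf("Two-outgroup K2P polarization model (n = %d), loglik %.3f\n",
              x$n, x$loglik))
  print(round(x$branch_params, 4))
  invisible(x)
}

#' Posterior probability that the major allele is ancestral
#'
#' Applies a fitted [fit_outgroup_model()] to a site table and returns,
#' for every site, the posterior probability that the major allele is the
#' ancestral state, together with the mutation class implied by each
#' orientation (S = G/C, W = A/T).
#'
#' @inheritParams fit_outgroup_model
#' @param model A fitted `outgroup_model`.
#' @return The input tibble plus `p_major_ancestral`,
#'   `class_major_ancestral` (class of the change if the major allele is
#'   ancestral; `NA` for monomorphic sites), and `class_minor_ancestral`.
#' @export
polarize <- function(sites, model) {
  stopifnot(inherits(model, "outgroup_model"))
  n <- model$n
  pat <- collapse_site_patterns(sites, n) |> select(-"count")
  T_arr <- k2p_triplet_array(as.vector(t(model$branch_params)))
  tt <- pattern_terms(pat, T_arr, model$prior, n)
  seg <- pat$minor != ""
  # For segregating sites, renormalize over the two observed alleles; for
  # monomorphic sites, over all four candidate ancestors.
  p <- ifelse(
    seg,
    tt$major / pmax(tt$major + tt$minor, 1e-300),
    tt$major / pmax(tt$total, 1e-300)
  )
  pat$p_major_ancestral <- p
  pat$class_major_ancestral <-
    ifelse(seg, mutation_class(pat$major, pat$minor), NA_character_)
  pat$class_minor_ancestral <-
    ifelse(seg, mutation_class(pat$minor, pat$major), NA_character_)
  sites |>
    mutate(minor_key = dplyr::coalesce(.data$minor, "")) |>
    left_join(pat, by = c(major = "major", minor_key = "minor",
                          major_count = "major_count",
                          o1 = "o1", o2 = "o2")) |>
    select(-"minor_key")
}

#' Build class-specific unfolded SFSs from polarized sites
#'
#' Each segregating site with minor-allele count `j_min` contributes
#' probability weight `p` (major ancestral) to the class of the
#' major-to-minor change at derived count `j_min`, and `1 - p` to the
#' opposite orientation at derived count `n - j_min`; weights sum to one
#' per site, so segregating-site mass is conserved exactly.  Monomorphic
#' sites increment the surveyed totals `L_W` or `L_S` by their fixed
#' allele's class.
#'
#' @param polarized Output of [polarize()].
#' @param n Haploid sample size.
#' @param round_counts Round the probability-weighted spectra to integers
#'   (default `FALSE`, keeping est-sfs-style expected counts).
#' @return A [class_sfs()].
#' @export
build_class_sfs <- function(polarized, n, round_counts = FALSE) {
  xi <- matrix(0, 3L, n - 1L, dimnames = list(SFS_CLASSES, NULL))
  seg <- !is.na(polarized$minor) & polarized$minor != ""
  pm <- polarized[seg, , drop = FALSE]
  if (nrow(pm) > 0) {
    j_min <- n - pm$major_count
    if (any(j_min < 1L | j_min > n - 1L)) {
      abort("Derived counts outside 1..n-1; check the site table.")
    }
    for (i in seq_len(nrow(pm))) {
      xi[pm$class_major_ancestral[i], j_min[i]] <-
        xi[pm$class_major_ancestral[i], j_min[i]] + pm$p_major_ancestral[i]
      xi[pm$class_minor_ancestral[i], n - j_min[i]] <-
        xi[pm$class_minor_ancestral[i], n - j_min[i]] +
        (1 - pm$p_major_ancestral[i])
    }
  }
  if (round_counts) xi <- round(xi)
  # surveyed totals: monomorphic sites plus the probability-weighted
  # ancestral allele of each segregating site
  mono <- polarized[!seg, , drop = FALSE]
  L_S <- sum(is_strong(mono$major))
  L_W <- nrow(mono) - L_S
  if (nrow(pm) > 0) {
    p <- pm$p_major_ancestral
    anc_strong <- p * is_strong(pm$major) + (1 - p) * is_strong(pm$minor)
    L_S <- L_S + sum(anc_strong)
    L_W <- L_W + sum(1 - anc_strong)
  }
  class_sfs(n, xi, L_W = L_W, L_S = L_S)
}
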