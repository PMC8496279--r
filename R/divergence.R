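# Nonstationary three-taxon substitution model and per-lineage labelled
# substitution counts via expected Markov counting.
#
# Tree: rooted ((ingroup, sister), outgroup) with the internal node -- the
# ingroup/sister common ancestor -- taken as the root.  The root (ancestral)
# base composition is a free parameter; each branch has its own target
# composition, shared GTR-style exchangeabilities, and its own length.
# Nonstationary models of this kind are root-identifiable, unlike the
# stationary GTR, which is also fitted to the same data for a likelihood
# ratio comparison.

# Collapse a site table into pattern counts over the three taxa.
site_pattern_counts <- function(data) {
  stopifnot(all(c("ingroup", "sister", "outgroup") %in% names(data)))
  ok <- data$ingroup %in% BASES & data$sister %in% BASES &
    data$outgroup %in% BASES
  data <- data[ok, , drop = FALSE]
  key <- paste(data$ingroup, data$sister, data$outgroup)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  tibble(
    ingroup = vapply(parts, `[`, "", 1L),
    sister = vapply(parts, `[`, "", 2L),
    outgroup = vapply(parts, `[`, "", 3L),
    count = as.numeric(tab)
  )
}

softmax4 <- function(z3) {
  z <- c(z3, 0)
  e <- exp(z - max(z))
  e / sum(e)
}

# Build exchangeability matrix from 5 free log-parameters (GT fixed at 1).
exch_matrix <- function(log_s5) {
  s <- exp(c(log_s5, 0))
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in seq_len(6)) {
    m[pairs[p, 1], pairs[p, 2]] <- m[pairs[p, 2], pairs[p, 1]] <- s[p]
  }
  m
}

triplet_loglik <- function(counts_mat, root_pi, P_list) {
  # counts_mat: pattern count tibble converted to integer state indices
  like <- numeric(nrow(counts_mat))
  Pi <- P_list$ingroup
  Ps <- P_list$sister
  Po <- P_list$outgroup
  a <- counts_mat$ia
  b <- counts_mat$is
  cc <- counts_mat$io
  for (x in 1:4) {
    like <- like + root_pi[x] * Pi[x, ] [a] * Ps[x, ][b] * Po[x, ][cc]
  }
  sum(counts_mat$count * log(pmax(like, 1e-300)))
}

prep_counts <- function(patterns) {
  patterns$ia <- match(patterns$ingroup, BASES)
  patterns$is <- match(patterns$sister, BASES)
  patterns$io <- match(patterns$outgroup, BASES)
  patterns
}

BRANCHES <- c("ingroup", "sister", "outgroup")

nonstat_unpack <- function(par, stationary = FALSE) {
  s5 <- par[1:5]
  root_pi <- softmax4(par[6:8])
  i <- 8L
  if (stationary) {
    branch_pi <- list(ingroup = root_pi, sister = root_pi,
                      outgroup = root_pi)
  } else {
    branch_pi <- list()
    for (b in BRANCHES) {
      branch_pi[[b]] <- softmax4(par[i + 1:3])
      i <- i + 3L
    }
  }
  t_len <- exp(par[i + 1:3])
  names(t_len) <- BRANCHES
  list(exch = exch_matrix(s5), root_pi = root_pi, branch_pi = branch_pi,
       t = t_len)
}

nonstat_negll <- function(par, counts, stationary = FALSE) {
  p <- nonstat_unpack(par, stationary)
  if (any(p$t > 20)) return(1e12)
  P_list <- list()
  for (b in BRANCHES) {
    Q <- ctmc_rate_matrix(p$exch, p$branch_pi[[b]])
    P_list[[b]] <- ctmc_prob_matrix(Q, p$t[[b]])
  }
  ll <- triplet_loglik(counts, p$root_pi, P_list)
  if (!is.finite(ll)) 1e12 else -ll
}

nonstat_init <- function(counts, stationary, jitter = 0) {
  comp <- function(states) {
    tab <- vapply(1:4, function(x) sum(counts$count[states == x]),
                  numeric(1))
    pmax(tab / sum(tab), 1e-3)
  }
  pi_ing <- comp(counts$ia)
  pi_sis <- comp(counts$is)
  pi_out <- comp(counts$io)
  pi_root <- (pi_ing + pi_sis) / 2
  pi_root <- pi_root / sum(pi_root)
  d_is <- sum(counts$count[counts$ia != counts$is]) / sum(counts$count)
  d_io <- sum(counts$count[counts$ia != counts$io]) / sum(counts$count)
  t0 <- pmax(c(d_is / 2, d_is / 2, d_io - d_is / 2), 5e-4)
  logit3 <- function(p) log(p[1:3] / p[4])
  par <- c(
    rep(0, 5),
    logit3(pi_root),
    if (!stationary) c(logit3(pi_ing), logit3(pi_sis), logit3(pi_out)),
    log(t0)
  )
  par + rnorm(length(par), 0, jitter)
}

#' Fit nonstationary and stationary three-taxon substitution models
#'
#' Maximum-likelihood fit of a composition-nonstationary GTR-style model to
#' three-taxon alignment columns: shared symmetric exchangeabilities, a
#' free root (ancestral) composition, and per-branch target compositions
#' and lengths.  The stationary GTR (one composition shared by the root
#' and all branches) is fitted to the same data, and both log-likelihoods
#' are stored so the models can be compared by a likelihood ratio test
#' (`lrt_nonstationary()`).  Optimization is quasi-Newton on transformed
#' parameters with `n_runs` jittered starts; the per-run best
#' log-likelihoods are kept as a convergence diagnostic.
#'
#' @param data A data frame of per-site alleles with columns `ingroup`,
#'   `sister`, `outgroup` (one row per alignment column), a pattern-count
#'   tibble with an additional `count` column, or a `triplet_sim`.
#' @param n_runs Number of jittered optimization runs (default 10).
#' @param seed Integer seed for the jitter.
#' @return A `nonstationary_model` object: exchangeabilities, root and
#'   per-branch compositions, branch lengths (expected substitutions per
#'   site at the branch target), `loglik`, `loglik_stationary`, and the
#'   per-run log-likelihood vectors.
#' @export
fit_nonstationary <- function(data, n_runs = 10L, seed = NULL) {
  if (inherits(data, "triplet_sim")) data <- data$sites
  patterns <- if ("count" %in% names(data)) data else site_pattern_counts(data)
  counts <- prep_counts(patterns)
  if (!is.null(seed)) set.seed(seed)

  run_fits <- function(stationary) {
    lls <- numeric(0)
    best <- NULL
    for (k in seq_len(max(1L, n_runs))) {
      init <- nonstat_init(counts, stationary,
                           jitter = if (k == 1L) 0 else 0.25)
      o <- tryCatch(
        optim(init, nonstat_negll, counts = counts, stationary = stationary,
              method = "BFGS", control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (is.null(o)) next
      lls <- c(lls, -o$value)
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) abort("All optimization runs failed to converge.")
    list(best = best, lls = lls)
  }

  ns <- run_fits(stationary = FALSE)
  st <- run_fits(stationary = TRUE)
  p <- nonstat_unpack(ns$best$par, stationary = FALSE)
  structure(
    list(
      exch = p$exch, root_pi = setNames(p$root_pi, BASES),
      branch_pi = lapply(p$branch_pi, setNames, BASES),
      branch_lengths = p$t,
      loglik = -ns$best$value, loglik_stationary = -st$best$value,
      run_logliks = ns$lls, run_logliks_stationary = st$lls,
      patterns = patterns, convergence = ns$best$convergence
    ),
    class = "nonstationary_model"
  )
}

#' @export
print.nonstationary_model <- function(x, ...) {
  cat(sprintf(
    "Nonstationary 3-taxon model: loglik %.3f (stationary GTR %.3f)\n",
    x$loglik, x$loglik_stationary
  ))
  cat("  branch lengths:",
      paste(sprintf("%s %.4f", BRANCHES, x$branch_lengths), collapse = ", "),
      "\n")
  cat("  root GC:", sprintf("%.3f", sum(x$root_pi[c("C", "G")])), "\n")
  invisible(x)
}

#' Likelihood ratio test of nonstationary vs stationary composition
#'
#' Compares the nonstationary fit (per-branch target compositions, free
#' root) against the stationary GTR fitted to the same data.  The
#' nonstationary model adds 9 composition parameters (three free branch
#' compositions of 3 d.f. each; the root composition replaces the shared
#' stationary one).
#'
#' @param model A `nonstationary_model` from [fit_nonstationary()].
#' @return A one-row tibble with `statistic`, `df`, and `p_value`.
#' @export
lrt_nonstationary <- function(model) {
  stopifnot(inherits(model, "nonstationary_model"))
  stat <- 2 * (model$loglik - model$loglik_stationary)
  if (stat < 0 && stat > -1e-4) stat <- 0
  df <- 9L
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Expected labelled substitution counts per lineage
#'
#' Combines the per-site posterior distribution over the ancestral
#' (root-node) state with the closed-form expected number of labelled
#' substitutions on each branch conditional on its endpoint states
#' ([emc_expected_counts()]), summed over sites.  Ancestral quantities are
#' posterior expectations -- sub-optimal ancestral states are integrated
#' over, never fixed to a single best reconstruction.  Counts are
#' partitioned into strong-to-weak (`n_sw`), weak-to-strong (`n_ws`) and
#' neutral (`n_neu`) changes; ancestral site totals `L_GC`, `L_AT` are
#' posterior-expected, and per-site rates are `r_sw = n_sw / L_GC`,
#' `r_ws = n_ws / L_AT` with ratio `R = r_sw / r_ws`.
#'
#' @param model A fitted `nonstationary_model`.
#' @param lineages Which branches to count along (default the two ingroup
#'   lineages).
#' @return A tibble with one row per lineage: labelled expected counts,
#'   ancestral base totals, rates, `R`, and the ancestral GC fraction.
#' @export
expected_substitution_counts <- function(model,
                                         lineages = c("ingroup", "sister")) {
  stopifnot(inherits(model, "nonstationary_model"))
  counts <- prep_counts(model$patterns)
  strong_state <- c(FALSE, TRUE, TRUE, FALSE)

  # posterior over the root state for every pattern
  P_list <- list()
  for (b in BRANCHES) {
    Q <- ctmc_rate_matrix(model$exch, model$branch_pi[[b]])
    P_list[[b]] <- list(Q = Q,
                        P = ctmc_prob_matrix(Q, model$branch_lengths[[b]]))
  }
  post <- matrix(0, nrow(counts), 4)
  for (x in 1:4) {
    post[, x] <- model$root_pi[x] *
      P_list$ingroup$P[x, ][counts$ia] *
      P_list$sister$P[x, ][counts$is] *
      P_list$outgroup$P[x, ][counts$io]
  }
  post <- post / pmax(rowSums(post), 1e-300)

  w <- counts$count
  L_GC <- sum(w * (post %*% strong_state))
  L_AT <- sum(w * (post %*% !strong_state))
  anc_gc <- L_GC / (L_GC + L_AT)

  out <- purrr::map_dfr(lineages, function(b) {
    emc <- emc_expected_counts(P_list[[b]]$Q, model$branch_lengths[[b]])
    end <- counts[[c(ingroup = "ia", sister = "is", outgroup = "io")[b]]]
    lab <- matrix(0, 4, 4) # label id per (i, j): 1 SW, 2 WS, 3 neu
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      lab[i, j] <- if (strong_state[i] && !strong_state[j]) 1L
      else if (!strong_state[i] && strong_state[j]) 2L else 3L
    }
    # per (root state a, end state b) expected labelled counts
    C_lab <- array(0, dim = c(4, 4, 3))
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      C_lab[, , lab[i, j]] <- C_lab[, , lab[i, j]] + emc$N[, , i, j]
    }
    tot <- numeric(3)
    for (l in 1:3) {
      # site-wise: sum_a post[s, a] * C_lab[a, end[s], l]
      m <- C_lab[, , l]
      tot[l] <- sum(w * rowSums(post * t(m)[end, , drop = FALSE]))
    }
    tibble(
      lineage = b, n_sw = tot[1], n_ws = tot[2], n_neu = tot[3],
      L_GC = L_GC, L_AT = L_AT,
      r_sw = tot[1] / L_GC, r_ws = tot[2] / L_AT,
      R = (tot[1] / L_GC) / (tot[2] / L_AT),
      ancestral_gc = anc_gc
    )
  })
  out
}
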