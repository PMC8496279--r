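# Poisson likelihood models for class-specific unfolded SFSs:
# semidominant directional force gamma, class mutation inputs theta,
# demographic distortion r_j, and optional polarization-error mixing.

GAMMA_MAX <- 50

# Binomial sampling kernel C(n, j) x^j (1-x)^{n-j} on the quadrature nodes,
# cached per (n, order).
.sfs_kernel_env <- new.env(parent = emptyenv())

sfs_kernel <- function(n, order = 64L) {
  key <- paste(n, order, sep = "_")
  if (is.null(.sfs_kernel_env[[key]])) {
    gl <- gl_rule(order)
    j <- seq_len(n - 1L)
    lb <- lchoose(n, j)
    B <- exp(outer(j, log(gl$x)) + outer(n - j, log1p(-gl$x)) + lb)
    .sfs_kernel_env[[key]] <- list(B = B, x = gl$x, w = gl$w)
  }
  .sfs_kernel_env[[key]]
}

# Shape of the expected unfolded SFS (theta = 1): the diffusion sojourn
# density of a semidominant mutation with scaled coefficient gamma, sampled
# binomially into n chromosomes.  Reduces to 1/j at gamma = 0.
sfs_shape <- function(gamma, n, order = 64L) {
  if (abs(gamma) > GAMMA_MAX) {
    abort(sprintf("|gamma| > %g exceeds the supported numeric range.", GAMMA_MAX))
  }
  j <- seq_len(n - 1L)
  if (abs(gamma) < 1e-12) return(1 / j)
  k <- sfs_kernel(n, order)
  h <- (1 - exp(-gamma * (1 - k$x))) / (-expm1(-gamma) * k$x * (1 - k$x))
  as.vector(k$B %*% (k$w * h))
}

#' Expected unfolded SFS under a semidominant directional force
#'
#' Expected derived-allele counts `E[xi_j]`, `j = 1..n-1`, for mutations
#' with scaled semidominant coefficient `gamma` and mutation input `theta`
#' (the expected-count scale):
#' `E[xi_j] = theta * C(n,j) * Int_0^1 h(x; gamma) x^j (1-x)^(n-j) dx` with
#' `h(x; gamma) = (1 - exp(-gamma (1-x))) / ((1 - exp(-gamma)) x (1-x))`,
#' the standard diffusion sojourn density.  The `gamma = 0` limit is the
#' neutral law `theta / j`.  A mutation class favored by the force uses
#' `+gamma`; the disfavored class uses `-gamma`.
#'
#' Integration uses a fixed-order Gauss-Legendre rule (the integrand is
#' smooth on (0, 1) for `j >= 1`; endpoint factors cancel analytically).
#'
#' @param gamma Scaled coefficient of the directional force (|gamma| <= 50).
#' @param theta Mutation input on the expected-count scale (>= 0).
#' @param n Haploid sample size.
#' @param order Gauss-Legendre order (default 64).
#' @return Numeric vector of length `n - 1` of expected counts.
#' @examples
#' expected_sfs(0, theta = 10, n = 5) # 10/j
#' @export
expected_sfs <- function(gamma, theta, n, order = 64L) {
  check_number(theta, "theta", lower = 0)
  check_number(gamma, "gamma")
  theta * sfs_shape(gamma, n, order)
}

# 3 x (n-1) matrix of model shapes per class: S>W is disfavored (-gamma),
# W>S favored (+gamma), neutral is the gamma -> 0 limit.
class_shapes <- function(gamma, n) {
  rbind(
    SW = sfs_shape(-gamma, n),
    WS = sfs_shape(gamma, n),
    neu = sfs_shape(0, n)
  )
}

# Cell means including distortion r_j and polarization-error mixing.
# eps may be a scalar or a named vector over classes; the observed cell of
# class c at frequency j is (1 - eps_c) m[c, j] + eps_opp(c) m[opp(c), n-j],
# with the neutral class its own opposite.
sfs_cell_means <- function(gamma, theta, r, eps, n) {
  m <- class_shapes(gamma, n) * theta[SFS_CLASSES]
  m <- sweep(m, 2L, r, "*")
  eps <- rep_len(eps, 3L)
  names(eps) <- SFS_CLASSES
  if (any(eps > 0)) {
    opp <- c(SW = "WS", WS = "SW", neu = "neu")
    refl <- m[opp, rev(seq_len(n - 1L)), drop = FALSE]
    rownames(refl) <- SFS_CLASSES
    m <- (1 - eps[SFS_CLASSES]) * m + eps[opp] * refl
  }
  m
}

#' Poisson log-likelihood of a class SFS under a fitted or candidate model
#'
#' Independent-Poisson likelihood over every class-by-frequency cell.  The
#' mean of cell `(c, j)` is `r_j * E[xi_j; gamma_c, theta_c]`, where the
#' distortion multipliers `r_j` (with `r_1 = 1` for identifiability) absorb
#' demographic departures from the standard neutral shape and are shared by
#' all three classes.  With polarization-error parameters (`M0*`/`M1*`),
#' observed cells mix each class with the frequency-reflected spectrum of
#' the opposite class.
#'
#' @param sfs A [class_sfs()] object.
#' @param fit A [gbgc_fit] or a list with elements `gamma`, `theta` (named
#'   `SW`, `WS`, `neu`), `r` (length `n - 1`), and optionally `eps`.
#' @return The log-likelihood (scalar; `-Inf` if a zero-mean cell has a
#'   positive observation).
#' @export
model_loglik <- function(sfs, fit) {
  stopifnot(inherits(sfs, "class_sfs"))
  eps <- fit$eps %||% 0
  r <- fit$r %||% rep(1, sfs$n - 1L)
  theta <- fit$theta
  if (is.null(names(theta))) names(theta) <- SFS_CLASSES
  m <- sfs_cell_means(fit$gamma %||% 0, theta, r, eps, sfs$n)
  poisson_cell_ll(sfs$xi, m)
}

# Poisson log-likelihood valid for fractional "expected" counts:
# x * log(m) - m - lgamma(x + 1).  Matches dpois exactly at integer x.
poisson_cell_ll <- function(x, m) {
  ll <- -m - lgamma(x + 1)
  pos <- x > 0
  ll[pos] <- ll[pos] + x[pos] * log(m[pos])
  ll[x > 0 & m <= 0] <- -Inf
  sum(ll)
}

# ---- Fitting ---------------------------------------------------------------

# Closed-form Poisson coordinate ascent over theta_c and r_j at fixed
# shapes (valid when eps = 0): each update is the exact conditional MLE, so
# the profile likelihood increases monotonically.
profile_theta_r <- function(x, shapes, tol = 1e-9, max_iter = 500L) {
  n1 <- ncol(x)
  theta <- rowSums(x) / pmax(rowSums(shapes), 1e-300)
  r <- rep(1, n1)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    E <- shapes * theta
    denom <- colSums(E)
    r <- ifelse(denom > 0, colSums(x) / denom, 1)
    r[1L] <- 1
    theta <- rowSums(x) / pmax(as.vector(shapes %*% r), 1e-300)
    m <- sweep(shapes * theta, 2L, r, "*")
    ll_new <- poisson_cell_ll(x, m)
    if (is.finite(ll_new) && ll_new - ll < tol && it > 2L) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(theta = theta, r = r, loglik = ll)
}

profile_loglik_gamma <- function(gamma, sfs) {
  profile_theta_r(sfs$xi, class_shapes(gamma, sfs$n))$loglik
}

new_gbgc_fit <- function(model, sfs, gamma, theta, r, eps, loglik,
                         convergence, restart_logliks) {
  names(theta) <- SFS_CLASSES
  kappa <- if (is.finite(sfs$L_S) && is.finite(sfs$L_W) &&
               theta[["WS"]] > 0) {
    (theta[["SW"]] / sfs$L_S) / (theta[["WS"]] / sfs$L_W)
  } else {
    NA_real_
  }
  np <- 3L + (sfs$n - 2L) +
    (if (model %in% c("M1", "M1*")) 1L else 0L) +
    (if (model %in% c("M0*", "M1*")) length(eps) else 0L)
  structure(
    list(
      model = model, n = sfs$n, gamma = gamma, kappa = kappa,
      theta = theta, r = r, eps = eps, loglik = loglik, np = np,
      L_W = sfs$L_W, L_S = sfs$L_S,
      convergence = convergence, restart_logliks = restart_logliks
    ),
    class = "gbgc_fit"
  )
}

#' Fit the directional-force SFS model to a class SFS
#'
#' Maximizes the Poisson likelihood of [model_loglik()] under one of four
#' nested models: `M0` (`gamma = 0`), `M1` (`gamma` free), and their
#' starred versions `M0*`/`M1*` which add polarization-error mixing
#' parameters `eps`.  The mutational bias is returned as the derived
#' quantity `kappa = (theta_SW / L_S) / (theta_WS / L_W)`.
#'
#' For `M0`/`M1` the class inputs `theta` and the distortions `r_j` are
#' profiled out in closed form (exact conditional Poisson MLEs), leaving a
#' one-dimensional search over `gamma`; restarts jitter the search grid.
#' The `gamma = 0` profile optimum is always included as a candidate for
#' `M1`, so `loglik(M1) >= loglik(M0)` by construction.  Starred models are
#' fitted by bounded quasi-Newton over log/logit-transformed parameters,
#' initialized from the corresponding non-star fit plus jittered restarts.
#'
#' @param sfs A [class_sfs()] object.
#' @param model One of `"M0"`, `"M1"`, `"M0*"`, `"M1*"`.
#' @param n_restarts Number of jittered starts (default 10).
#' @param seed Integer seed controlling the jitter.
#' @param eps_by_class For starred models, estimate one misorientation
#'   probability per class instead of a single shared one.
#' @return A `gbgc_fit` object; see [tidy.gbgc_fit()] and
#'   [glance.gbgc_fit()].
#' @export
fit_sfs_model <- function(sfs, model = c("M1", "M0", "M0*", "M1*"),
                          n_restarts = 10L, seed = NULL,
                          eps_by_class = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(sfs, "class_sfs"))
  if (all(rowSums(sfs$xi) == 0)) abort("SFS has no segregating sites.")
  if (!is.null(seed)) set.seed(seed)
  n <- sfs$n

  if (model == "M0") {
    pf <- profile_theta_r(sfs$xi, class_shapes(0, n))
    return(new_gbgc_fit("M0", sfs, 0, pf$theta, pf$r, NULL, pf$loglik,
                        0L, pf$loglik))
  }

  if (model == "M1") {
    grid <- c(0, seq(-8, 8, by = 1))
    if (n_restarts > 1L) {
      grid <- c(grid, runif(n_restarts - 1L, -12, 12))
    }
    grid <- unique(pmin(pmax(grid, -GAMMA_MAX + 1), GAMMA_MAX - 1))
    ll_grid <- vapply(grid, profile_loglik_gamma, numeric(1), sfs = sfs)
    best <- grid[which.max(ll_grid)]
    lo <- max(best - 2, -GAMMA_MAX + 0.5)
    hi <- min(best + 2, GAMMA_MAX - 0.5)
    opt <- optimize(profile_loglik_gamma, c(lo, hi), sfs = sfs,
                    maximum = TRUE, tol = 1e-7)
    cand <- rbind(
      c(opt$maximum, opt$objective),
      c(best, max(ll_grid)),
      c(0, ll_grid[grid == 0][1])
    )
    g_hat <- cand[which.max(cand[, 2]), 1]
    pf <- profile_theta_r(sfs$xi, class_shapes(g_hat, n))
    return(new_gbgc_fit("M1", sfs, g_hat, pf$theta, pf$r, NULL, pf$loglik,
                        0L, ll_grid))
  }

  # Starred models: full optimization over transformed parameters.
  base <- fit_sfs_model(sfs, if (model == "M0*") "M0" else "M1",
                        n_restarts = n_restarts, seed = seed)
  n_eps <- if (eps_by_class) 3L else 1L
  free_gamma <- model == "M1*"

  unpack <- function(par) {
    theta <- exp(par[1:3])
    r <- c(1, exp(par[3L + seq_len(n - 2L)]))
    i <- 3L + (n - 2L)
    gamma <- if (free_gamma) par[i + 1L] else 0
    if (free_gamma) i <- i + 1L
    eps <- 0.5 * stats::plogis(par[i + seq_len(n_eps)])
    list(gamma = gamma, theta = theta, r = r, eps = eps)
  }
  negll <- function(par) {
    p <- unpack(par)
    if (abs(p$gamma) > GAMMA_MAX - 0.5) return(1e12)
    m <- sfs_cell_means(p$gamma, setNames(p$theta, SFS_CLASSES),
                        p$r, p$eps, n)
    ll <- poisson_cell_ll(sfs$xi, m)
    if (!is.finite(ll)) 1e12 else -ll
  }
  pack_init <- function(jitter = 0) {
    c(
      log(pmax(base$theta, 1e-8)) + rnorm(3, 0, jitter),
      log(pmax(base$r[-1L], 1e-8)) + rnorm(n - 2L, 0, jitter),
      if (free_gamma) base$gamma + rnorm(1, 0, jitter),
      rep(stats::qlogis(2 * 0.02), n_eps) + rnorm(n_eps, 0, jitter)
    )
  }
  best <- NULL
  lls <- numeric(0)
  for (k in seq_len(max(1L, n_restarts))) {
    init <- pack_init(jitter = if (k == 1L) 0 else 0.3)
    o <- tryCatch(
      optim(init, negll, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    lls <- c(lls, -o$value)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) abort("All optimization starts failed.")
  p <- unpack(best$par)
  fit <- new_gbgc_fit(model, sfs, p$gamma, p$theta, p$r, p$eps,
                      -best$value, best$convergence, lls)
  # A boundary fit at eps = 0 can only match, never beat, the nested
  # non-star optimum; keep whichever likelihood is higher.
  if (fit$loglik < base$loglik) {
    fit <- new_gbgc_fit(model, sfs, base$gamma, base$theta, base$r,
                        rep(0, n_eps), base$loglik, 0L, lls)
  }
  fit
}

#' @export
print.gbgc_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit (n = %d): gamma = %.4g, kappa = %.4g, loglik = %.3f\n",
    x$model, x$n, x$gamma, x$kappa, x$loglik
  ))
  invisible(x)
}

#' Tidy a directional-force SFS model fit
#'
#' @param x A `gbgc_fit` from [fit_sfs_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `type`).
#' @export
tidy.gbgc_fit <- function(x, ...) {
  rows <- list(
    tibble(term = c("gamma", "kappa"),
           estimate = c(x$gamma, x$kappa), type = "primary"),
    tibble(term = paste0("theta_", names(x$theta)),
           estimate = unname(x$theta), type = "mutation_input"),
    tibble(term = paste0("r_", seq_along(x$r)),
           estimate = unname(x$r), type = "distortion")
  )
  if (!is.null(x$eps)) {
    rows <- c(rows, list(tibble(
      term = if (length(x$eps) == 1L) "eps" else paste0("eps_", SFS_CLASSES),
      estimate = unname(x$eps), type = "polarization_error"
    )))
  }
  bind_rows(rows)
}

#' One-row summary of a directional-force SFS model fit
#'
#' @inheritParams tidy.gbgc_fit
#' @return A one-row tibble with the model tag, point estimates, the
#'   log-likelihood, parameter count, and convergence flag.
#' @export
glance.gbgc_fit <- function(x, ...) {
  tibble(
    model = x$model, n = x$n, gamma = x$gamma, kappa = x$kappa,
    loglik = x$loglik, np = x$np, convergence = x$convergence
  )
}

#' Likelihood-ratio test between nested SFS models
#'
#' Compares two fits of the same class SFS for the nested pairs
#' M0 in M1, M0* in M1*, M0 in M0*, and M1 in M1*.  The statistic is
#' `2 * (loglik_alt - loglik_null)` with degrees of freedom equal to the
#' difference in parameter counts, referred to a chi-squared distribution.
#'
#' @param fit_null,fit_alt `gbgc_fit` objects for the null and alternative
#'   models, fitted to the same data.
#' @return A one-row tibble with `statistic`, `df`, and `p_value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "gbgc_fit"), inherits(fit_alt, "gbgc_fit"))
  allowed <- list(
    c("M0", "M1"), c("M0*", "M1*"), c("M0", "M0*"), c("M1", "M1*"),
    c("M0", "M1*")
  )
  pair <- c(fit_null$model, fit_alt$model)
  if (!any(vapply(allowed, identical, logical(1), y = pair))) {
    abort(sprintf("Models %s and %s are not a nested null/alternative pair.",
                  pair[1], pair[2]))
  }
  if (fit_null$n != fit_alt$n) abort("Fits have different sample sizes.")
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < 0 && stat > -1e-4) stat <- 0
  df <- fit_alt$np - fit_null$np
  tibble(
    statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE)
  )
}
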