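# Synthetic polymorphism and divergence data with known ground truth.
#
# The generator emulates the structure of the real study inputs: ~9327
# short introns of 23 bp of near-neutral sites, a focal-population haploid
# sample, a sister species and one outgroup, weak/strong-asymmetric
# mutation with bias kappa, a semidominant GC-favoring force gamma, SFS
# distortion by demography, and polarization error.

#' Configuration for the synthetic-data generator
#'
#' Collects the ground-truth parameters and the seed for all synthetic
#' data.  Defaults describe a mutation-fixation equilibrium population:
#' `kappa = 3`, `gamma = 0` (so target GC is 0.25), class mutation inputs
#' on the scale of the empirical study (tens of thousands of segregating
#' sites over ~214 kb of short-intron sites), a haploid sample of 21, and
#' divergence branch lengths comparable to the focal species pair plus a
#' more distant outgroup.
#'
#' @param gamma Scaled semidominant coefficient of the GC-favoring force
#'   (`4*Ne*s`, dimensionless).
#' @param kappa Mutational bias `u/v` (S>W over W>S per-site rate).
#' @param theta_ws,theta_sw,theta_neu Class mutation inputs on the
#'   expected-count scale (aggregate over all surveyed sites).
#' @param n Haploid sample size.
#' @param distortion Optional vector of per-frequency-class multipliers
#'   `r_j`, `j = 1..n-1` (all positive); `NULL` means no distortion.
#' @param polarization_error Per-class misorientation probability in
#'   `[0, 0.5)`.
#' @param n_introns Number of introns.
#' @param intron_length Number of analyzable sites per intron (bp).
#' @param gc_distribution Optional per-intron target GC fractions (length
#'   `n_introns`); `NULL` uses the equilibrium value
#'   `gc_equilibrium(kappa, gamma)` for every intron.
#' @param branch_lengths Named vector of expected substitutions per site
#'   for the `ingroup`, `sister`, and `outgroup` branches of the rooted
#'   three-taxon tree (root = ingroup/sister common ancestor).
#' @param branch_gc Optional named list of per-branch target GC fractions
#'   (scalar or per-intron), to simulate nonstationary composition; `NULL`
#'   keeps every branch at the intron's target GC.
#' @param seed Integer master seed; identical config + seed gives
#'   bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(gamma = 0, kappa = 3,
                       theta_ws = 4000, theta_sw = 4000, theta_neu = 4000,
                       n = 21L, distortion = NULL, polarization_error = 0,
                       n_introns = 9327L, intron_length = 23L,
                       gc_distribution = NULL,
                       branch_lengths = c(ingroup = 0.058, sister = 0.066,
                                          outgroup = 0.25),
                       branch_gc = NULL, seed = 1L) {
  check_number(gamma, "gamma", lower = -GAMMA_MAX, upper = GAMMA_MAX)
  check_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_number(theta_ws, "theta_ws", lower = 0)
  check_number(theta_sw, "theta_sw", lower = 0)
  check_number(theta_neu, "theta_neu", lower = 0)
  check_number(polarization_error, "polarization_error", lower = 0,
               upper = 0.5, strict_upper = TRUE)
  n <- as.integer(n)
  if (n < 2L) abort("`n` must be >= 2.")
  if (!is.null(distortion)) {
    if (length(distortion) != n - 1L || any(distortion <= 0)) {
      abort("`distortion` must have length n - 1 with positive entries.")
    }
  }
  n_introns <- as.integer(n_introns)
  intron_length <- as.integer(intron_length)
  if (n_introns < 1L || intron_length < 1L) {
    abort("`n_introns` and `intron_length` must be positive.")
  }
  if (!is.null(gc_distribution)) {
    gc_distribution <- rep_len(gc_distribution, n_introns)
    if (any(gc_distribution <= 0 | gc_distribution >= 1)) {
      abort("`gc_distribution` values must be strictly inside (0, 1).")
    }
  }
  if (!all(c("ingroup", "sister", "outgroup") %in% names(branch_lengths)) ||
      any(branch_lengths < 0)) {
    abort("`branch_lengths` needs non-negative ingroup/sister/outgroup entries.")
  }
  structure(
    list(
      gamma = gamma, kappa = kappa, theta_ws = theta_ws,
      theta_sw = theta_sw, theta_neu = theta_neu, n = n,
      distortion = distortion, polarization_error = polarization_error,
      n_introns = n_introns, intron_length = intron_length,
      gc_distribution = gc_distribution,
      branch_lengths = branch_lengths[c("ingroup", "sister", "outgroup")],
      branch_gc = branch_gc, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Surveyed W/S site totals consistent with kappa and the theta's:
# kappa = (theta_sw / L_S) / (theta_ws / L_W), L_W + L_S = total sites.
surveyed_totals <- function(config) {
  total <- config$n_introns * config$intron_length
  rho <- if (config$theta_ws > 0) {
    config$theta_sw / (config$kappa * config$theta_ws)
  } else {
    config$kappa # degenerate; only the sum matters downstream
  }
  L_S <- total * rho / (1 + rho)
  c(L_W = total - L_S, L_S = L_S)
}

#' Simulate a class-specific unfolded SFS with known parameters
#'
#' Draws every class-by-frequency cell as an independent Poisson around the
#' model expectation of [expected_sfs()], after applying the demographic
#' distortion multipliers `r_j` and polarization-error mixing from the
#' configuration.  Surveyed W/S site totals are returned consistent with
#' `kappa` and the theta's, so that [fit_sfs_model()] can recover `kappa`
#' as a derived quantity.
#'
#' @param config A [sim_config()].
#' @return A [class_sfs()] with attribute `"expected"` holding the
#'   noise-free cell means.
#' @export
simulate_class_sfs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "sfs"))
  theta <- c(SW = config$theta_sw, WS = config$theta_ws,
             neu = config$theta_neu)
  r <- config$distortion %||% rep(1, config$n - 1L)
  m <- sfs_cell_means(config$gamma, theta, r, config$polarization_error,
                      config$n)
  xi <- matrix(rpois(length(m), m), nrow = nrow(m),
               dimnames = dimnames(m))
  L <- surveyed_totals(config)
  out <- class_sfs(config$n, xi, L_W = L[["L_W"]], L_S = L[["L_S"]])
  attr(out, "expected") <- m
  out
}

#' Forward Wright-Fisher oracle for the expected SFS
#'
#' Independent check of the diffusion expectation in [expected_sfs()]:
#' forward simulation of a haploid Wright-Fisher population of size
#' `pop_size` with semidominant selection (per-copy sampling advantage
#' `sigma = gamma / (2 * pop_size)`, which matches the diffusion fixation
#' probability `(1 - exp(-gamma * p)) / (1 - exp(-gamma))`).  Each
#' replicate injects one new mutation at frequency `1 / pop_size` and
#' tracks it to absorption; sojourn generations are accumulated per
#' population count and converted to an expected sample SFS by
#' hypergeometric sampling (without replacement) into `n` chromosomes,
#' with mutation inflow scaled so the neutral case gives `theta / j`.
#'
#' @inheritParams expected_sfs
#' @param pop_size Haploid population size (at least `50 * n`
#'   recommended; smaller values trigger a warning).
#' @param reps Number of independent mutation trajectories.
#' @param seed Integer seed.
#' @return A tibble with columns `j` and `count` (the empirical expected
#'   SFS on the same scale as `expected_sfs(gamma, theta, n)`).
#' @export
wright_fisher_oracle <- function(gamma, n, pop_size, reps = 1e5,
                                 seed = NULL, theta = 1) {
  check_number(gamma, "gamma")
  pop_size <- as.integer(pop_size)
  if (pop_size < 50L * n) {
    warn("`pop_size` below 50 * n; diffusion approximation may be coarse.")
  }
  if (!is.null(seed)) set.seed(seed)
  M <- pop_size
  sigma <- gamma / (2 * M)
  H <- numeric(M - 1L) # sojourn generations at derived count 1..M-1
  cnt <- rep(1L, as.integer(reps))
  while (length(cnt) > 0L) {
    H <- H + tabulate(cnt, nbins = M - 1L)
    p <- cnt / M
    p_sel <- p * (1 + sigma) / (1 + p * sigma)
    cnt <- rbinom(length(cnt), M, p_sel)
    cnt <- cnt[cnt > 0L & cnt < M]
  }
  # Stationary flux: theta = 2 * M * (per-copy rate) implies a
  # population-wide inflow of theta / 2 new mutations per generation.
  nu <- theta / 2
  occupied <- which(H > 0)
  xi <- nu / reps * vapply(seq_len(n - 1L), function(j) {
    sum(H[occupied] * dhyper(j, occupied, M - occupied, n))
  }, numeric(1))
  if (sum(xi) == 0) warn("No sojourn mass reached the sample SFS; increase `reps`.")
  tibble(j = seq_len(n - 1L), count = xi)
}

# ---- Three-taxon alignment simulation --------------------------------------

base_freqs_from_gc <- function(g) {
  # pi over A, C, G, T for target GC fraction g
  cbind((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
}

# Vectorized Gillespie evolution of independent sites along one branch of a
# composition-targeted CTMC with unit exchangeabilities: q_ij = pi_j for
# j != i, rescaled so that one unit of branch length equals one expected
# substitution per site at the target composition.
# Returns end states plus per-site labelled jump counts.
evolve_branch <- function(states, t_len, g) {
  S <- length(states)
  g <- rep_len(g, S)
  mu <- 1 - ((1 - g)^2 + g^2) / 2 # stationary substitution rate, unscaled
  n_sw <- n_ws <- n_neu <- integer(S)
  rem <- rep(t_len, S)
  active <- seq_len(S)
  st <- states
  strong_state <- c(FALSE, TRUE, TRUE, FALSE) # A C G T
  while (length(active) > 0L) {
    cur <- st[active]
    g_a <- g[active]
    pi_cur <- ifelse(strong_state[cur], g_a / 2, (1 - g_a) / 2)
    lambda <- (1 - pi_cur) / mu[active]
    wait <- rexp(length(active), lambda)
    rem[active] <- rem[active] - wait
    jumped <- rem[active] > 0
    if (any(jumped)) {
      ja <- active[jumped]
      cur_j <- st[ja]
      g_j <- g[ja]
      # target probabilities proportional to pi_j over the 3 other states
      pi_all <- base_freqs_from_gc(g_j)
      pi_all[cbind(seq_along(ja), cur_j)] <- 0
      pi_all <- pi_all / rowSums(pi_all)
      u <- runif(length(ja))
      cum1 <- pi_all[, 1]
      cum2 <- cum1 + pi_all[, 2]
      cum3 <- cum2 + pi_all[, 3]
      new_st <- 1L + (u > cum1) + (u > cum2) + (u > cum3)
      s_old <- strong_state[cur_j]
      s_new <- strong_state[new_st]
      n_sw[ja] <- n_sw[ja] + (s_old & !s_new)
      n_ws[ja] <- n_ws[ja] + (!s_old & s_new)
      n_neu[ja] <- n_neu[ja] + (s_old == s_new)
      st[ja] <- new_st
    }
    active <- active[jumped]
  }
  list(states = st, n_sw = n_sw, n_ws = n_ws, n_neu = n_neu)
}

#' Simulate three-taxon alignments with a polymorphism overlay
#'
#' For each intron, draws a root (ingroup/sister common ancestor) sequence
#' from the intron's target composition and evolves it independently along
#' the three branches of the rooted tree ((ingroup, sister), outgroup)
#' under a weak/strong-asymmetric substitution model: unit exchangeabilities
#' with branch-specific target GC, which is nonstationary whenever a
#' branch's target differs from the root composition.  True per-branch
#' substitution counts are recorded by label (S>W, W>S, neutral).  A
#' polymorphism sample for the focal (ingroup) species is then overlaid
#' from [simulate_class_sfs()]: segregating sites replace fixed states (a
#' site is either polymorphic or fixed, never both).
#'
#' @param config A [sim_config()].
#' @return A list of class `triplet_sim` with elements `sites` (tibble:
#'   intron, position, true ancestor, ingroup/sister/outgroup alleles),
#'   `haplotypes` (`n` x sites character matrix for the focal sample),
#'   `truth` (per-intron, per-branch labelled substitution counts),
#'   `polymorphisms` (per segregating site: class, derived count,
#'   ancestral/derived alleles), `sfs` (the overlaid [class_sfs()]), and
#'   the `config`.
#' @export
simulate_triplet_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sfs <- simulate_class_sfs(config) # own derived seed; deterministic
  set.seed(derive_seed(config$seed, "triplet"))
  n_int <- config$n_introns
  len <- config$intron_length
  S <- n_int * len
  gc_int <- config$gc_distribution %||%
    rep(gc_equilibrium(config$kappa, config$gamma), n_int)
  g_site <- rep(gc_int, each = len)
  intron <- rep(seq_len(n_int), each = len)

  # root sequence from per-intron composition
  pi_root <- base_freqs_from_gc(g_site)
  u <- runif(S)
  root <- 1L + (u > pi_root[, 1]) +
    (u > pi_root[, 1] + pi_root[, 2]) +
    (u > pi_root[, 1] + pi_root[, 2] + pi_root[, 3])

  branch_gc <- function(branch) {
    bg <- config$branch_gc[[branch]] %||% gc_int
    rep(rep_len(bg, n_int), each = len)
  }
  branches <- list()
  for (b in c("ingroup", "sister", "outgroup")) {
    branches[[b]] <- evolve_branch(root, config$branch_lengths[[b]],
                                   branch_gc(b))
  }

  # polymorphism overlay on the ingroup: assign each simulated segregating
  # site to an eligible ingroup site (ancestral allele of the right class),
  # preferring sites carrying no ingroup-branch substitution; a chosen site
  # that did carry one has it erased (reverted to the root state).
  xi <- sfs$xi
  ing <- branches$ingroup
  ing_states <- ing$states
  strong_state <- c(FALSE, TRUE, TRUE, FALSE)
  poly <- vector("list", 3L)
  names(poly) <- SFS_CLASSES
  taken <- logical(S)
  for (cl in SFS_CLASSES) {
    need <- sum(xi[cl, ])
    if (need == 0) next
    eligible <- if (cl == "SW") {
      strong_state[ing_states]
    } else if (cl == "WS") {
      !strong_state[ing_states]
    } else {
      rep(TRUE, S)
    }
    eligible <- which(eligible & !taken)
    clean <- eligible[ing$n_sw[eligible] + ing$n_ws[eligible] +
                        ing$n_neu[eligible] == 0L]
    dirty <- setdiff(eligible, clean)
    pool <- c(clean[sample.int(length(clean))],
              dirty[sample.int(length(dirty))])
    if (need > length(pool)) {
      warn(sprintf("Only %d of %d requested %s polymorphisms placed.",
                   length(pool), need, cl))
      need <- length(pool)
    }
    chosen <- pool[seq_len(need)]
    taken[chosen] <- TRUE
    js <- rep(seq_len(config$n - 1L), xi[cl, ])[seq_len(need)]
    poly[[cl]] <- tibble(site = chosen, class = cl, j = js)
  }
  poly <- bind_rows(poly)

  if (nrow(poly) > 0) {
    # revert any ingroup-branch substitution at polymorphic sites
    idx <- poly$site
    reverted <- ing$n_sw[idx] + ing$n_ws[idx] + ing$n_neu[idx] > 0L
    ing$n_sw[idx] <- ing$n_ws[idx] <- ing$n_neu[idx] <- 0L
    ing_states[idx] <- root[idx]
    # draw derived alleles of the required class
    anc <- ing_states[idx]
    der <- vapply(seq_len(nrow(poly)), function(i) {
      a <- anc[i]
      cand <- switch(poly$class[i],
        SW = c(1L, 4L),
        WS = c(2L, 3L),
        neu = if (strong_state[a]) setdiff(c(2L, 3L), a) else setdiff(c(1L, 4L), a)
      )
      cand <- setdiff(cand, a)
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, integer(1))
    poly$anc <- BASES[anc]
    poly$der <- BASES[der]
  }
  branches$ingroup <- ing

  # focal-sample haplotypes: ingroup allele everywhere, derived allele in j
  # randomly chosen haplotypes at each polymorphic site
  hap <- matrix(rep(BASES[ing_states], each = config$n),
                nrow = config$n, ncol = S)
  if (nrow(poly) > 0) {
    for (i in seq_len(nrow(poly))) {
      carriers <- sample.int(config$n, poly$j[i])
      hap[carriers, poly$site[i]] <- poly$der[i]
    }
  }

  sites <- tibble(
    site = seq_len(S),
    intron_id = intron,
    position = rep(seq_len(len), n_int),
    target_gc = g_site,
    ancestor = BASES[root],
    ingroup = BASES[ing_states],
    sister = BASES[branches$sister$states],
    outgroup = BASES[branches$outgroup$states]
  )

  truth <- purrr::map_dfr(
    c("ingroup", "sister", "outgroup"),
    function(b) {
      br <- branches[[b]]
      tibble(intron_id = intron, branch = b, n_sw = br$n_sw,
             n_ws = br$n_ws, n_neu = br$n_neu)
    }
  ) |>
    group_by(.data$intron_id, .data$branch) |>
    summarise(across(c("n_sw", "n_ws", "n_neu"), sum), .groups = "drop") |>
    mutate(n_total = .data$n_sw + .data$n_ws + .data$n_neu)

  structure(
    list(sites = sites, haplotypes = hap, truth = truth,
         polymorphisms = poly, sfs = sfs, config = config),
    class = "triplet_sim"
  )
}

#' Site table for ancestral-allele inference from a simulated dataset
#'
#' Collapses a [simulate_triplet_alignment()] result into the per-site
#' table consumed by [fit_outgroup_model()] and [polarize()]: ingroup
#' major/minor alleles and counts plus the two outgroup alleles (the
#' sister-species and outgroup reference states).
#'
#' @param sim A `triplet_sim` object.
#' @return A tibble with columns `site`, `major`, `minor`, `major_count`,
#'   `minor_count`, `o1`, `o2`.
#' @export
triplet_sites <- function(sim) {
  stopifnot(inherits(sim, "triplet_sim"))
  n <- sim$config$n
  S <- ncol(sim$haplotypes)
  major <- sim$sites$ingroup
  minor <- rep(NA_character_, S)
  major_count <- rep(n, S)
  if (nrow(sim$polymorphisms) > 0) {
    p <- sim$polymorphisms
    der_count <- p$j
    anc_major <- der_count <= n - der_count
    major[p$site] <- ifelse(anc_major, p$anc, p$der)
    minor[p$site] <- ifelse(anc_major, p$der, p$anc)
    major_count[p$site] <- pmax(der_count, n - der_count)
  }
  tibble(
    site = seq_len(S), major = major, minor = minor,
    major_count = major_count, minor_count = n - major_count,
    o1 = sim$sites$sister, o2 = sim$sites$outgroup
  )
}

#' Write a simulated dataset to disk as FASTA alignments plus truth tables
#'
#' Emits one multi-FASTA per intron (the `n` sampled haplotypes plus the
#' sister and outgroup reference sequences), a tab-separated per-branch
#' truth table of labelled substitution counts, and a JSON echo of the
#' configuration.  All coordinates are 0-based half-open.
#'
#' @param sim A `triplet_sim` object.
#' @param dir Output directory (created if missing).
#' @param introns Which introns to write (default: all).
#' @return Invisibly, the output directory.
#' @export
write_triplet_fasta <- function(sim, dir, introns = NULL) {
  stopifnot(inherits(sim, "triplet_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  len <- sim$config$intron_length
  introns <- introns %||% seq_len(sim$config$n_introns)
  for (i in introns) {
    cols <- which(sim$sites$intron_id == i)
    seqs <- c(
      apply(sim$haplotypes[, cols, drop = FALSE], 1L, paste, collapse = ""),
      paste(sim$sites$sister[cols], collapse = ""),
      paste(sim$sites$outgroup[cols], collapse = "")
    )
    names(seqs) <- c(sprintf("sample_%02d", seq_len(sim$config$n)),
                     "sister_ref", "outgroup_ref")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(seqs),
      filepath = file.path(dir, sprintf("intron_%05d.fa", i))
    )
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth_substitutions.tsv"))
  cfg <- sim$config
  cfg$distortion <- as.numeric(cfg$distortion)
  cfg$gc_distribution <- as.numeric(cfg$gc_distribution)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
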