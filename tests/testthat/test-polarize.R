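manual_model <- function(params, n, prior = NULL) {
  structure(
    list(
      branch_params = matrix(params, nrow = 3L, byrow = TRUE,
                             dimnames = list(c("ingroup", "outgroup1",
                                               "outgroup2"),
                                             c("transition",
                                               "transversion"))),
      prior = prior %||% rep(1 / (n + 1), n + 1L),
      n = n, loglik = NA_real_, restart_logliks = numeric(0),
      convergence = 0L
    ),
    class = "outgroup_model"
  )
}

test_that("concordant outgroups on short branches give near-certain polarization", {
  n <- 10L
  sites <- tibble::tibble(
    site = 1:2, major = "A", minor = c(NA, "G"),
    major_count = c(10L, 7L), minor_count = c(0L, 3L),
    o1 = "A", o2 = "A"
  )
  model <- manual_model(rep(1e-6, 6), n)
  pol <- polarize(sites, model)
  expect_true(all(pol$p_major_ancestral > 0.999))
  expect_equal(pol$class_major_ancestral[2], "WS")
  expect_equal(pol$class_minor_ancestral[2], "SW")
})

test_that("perfectly symmetric evidence gives p = 0.5", {
  n <- 10L
  sites <- tibble::tibble(
    site = 1L, major = "A", minor = "G",
    major_count = 5L, minor_count = 5L, o1 = "A", o2 = "G"
  )
  # symmetric prior and equal branch parameters on the two outgroups
  prior <- rep(1 / (n + 1), n + 1L)
  model <- manual_model(c(0.05, 0.05, 0.2, 0.2, 0.2, 0.2), n, prior)
  pol <- polarize(sites, model)
  expect_equal(pol$p_major_ancestral, 0.5, tolerance = 1e-10)
})

test_that("posteriors equal brute-force summation over ancestral states", {
  n <- 6L
  sites <- tibble::tibble(
    site = 1:4,
    major = c("A", "C", "G", "T"),
    minor = c("G", "T", "C", NA),
    major_count = c(4L, 5L, 3L, 6L),
    minor_count = c(2L, 1L, 3L, 0L),
    o1 = c("A", "C", "C", "T"),
    o2 = c("G", "T", "C", "C")
  )
  params <- c(0.08, 0.03, 0.15, 0.06, 0.3, 0.12)
  prior <- c(0.5, 0.2, 0.1, 0.06, 0.05, 0.04, 0.05)
  model <- manual_model(params, n, prior)
  pol <- polarize(sites, model)

  # independent enumeration: sum over ingroup-ancestor z and node state y
  P1 <- sispec:::k2p_matrix(params[1], params[2])
  P2 <- sispec:::k2p_matrix(params[3], params[4])
  P3 <- sispec:::k2p_matrix(params[5], params[6])
  bases <- c("A", "C", "G", "T")
  for (s in 1:4) {
    st <- sites[s, ]
    lik_z <- setNames(numeric(4), bases)
    for (z in bases) {
      w <- if (is.na(st$minor)) {
        if (z == st$major) prior[1] else prior[n + 1]
      } else if (z == st$major) {
        prior[st$minor_count + 1]
      } else if (z == st$minor) {
        prior[st$major_count + 1]
      } else {
        0
      }
      tree <- 0
      for (y in bases) {
        tree <- tree + 0.25 * P1[y, z] * P2[y, st$o1] * P3[y, st$o2]
      }
      lik_z[z] <- w * tree
    }
    expected_p <- if (is.na(st$minor)) {
      lik_z[st$major] / sum(lik_z)
    } else {
      lik_z[st$major] / (lik_z[st$major] + lik_z[st$minor])
    }
    expect_equal(pol$p_major_ancestral[s], unname(expected_p),
                 tolerance = 1e-12)
  }
})

test_that("class SFS construction conserves mass and splits orientations", {
  n <- 10L
  pol <- tibble::tibble(
    site = 1:3, major = c("G", "C", "A"), minor = c("A", "G", "T"),
    major_count = c(7L, 8L, 6L), minor_count = c(3L, 2L, 4L),
    o1 = "A", o2 = "A",
    p_major_ancestral = c(1, 0.5, 0.25),
    class_major_ancestral = mutation_class(c("G", "C", "A"),
                                           c("A", "G", "T")),
    class_minor_ancestral = mutation_class(c("A", "G", "T"),
                                           c("G", "C", "A"))
  )
  sfs <- build_class_sfs(pol, n)
  expect_equal(sum(sfs$xi), 3)
  # site 1: derived A at count 3, p = 1, class S>W
  expect_equal(unname(sfs$xi["SW", 3]), 1)
  # site 2: C/G change is neutral in both orientations: 0.5 at j = 2 and 8
  expect_equal(unname(sfs$xi["neu", 2]), 0.5)
  expect_equal(unname(sfs$xi["neu", 8]), 0.5)
  # site 3: A>T neutral with p 0.25 at j = 4; T>A neutral 0.75 at j = 6
  expect_equal(unname(sfs$xi["neu", 4]), 0.25)
  expect_equal(unname(sfs$xi["neu", 6]), 0.75)
})

test_that("fitting on simulated data is convergent and polarizes accurately", {
  cfg <- sim_config(gamma = 0, kappa = 3, theta_ws = 250, theta_sw = 250,
                    theta_neu = 250, n = 21L, n_introns = 400L, seed = 19)
  sim <- simulate_triplet_alignment(cfg)
  sites <- triplet_sites(sim)
  model <- fit_outgroup_model(sites, n = 21L, n_restarts = 10, seed = 2)
  # restarts agree on the optimum
  best <- max(model$restart_logliks)
  expect_lt(best - sort(model$restart_logliks, decreasing = TRUE)[2], 1e-4)

  pol <- polarize(sites, model)
  seg <- !is.na(pol$minor)
  expect_equal(sum(seg), nrow(sim$polymorphisms))
  # mass conservation: weighted SFS sums to the number of segregating sites
  sfs <- build_class_sfs(pol, n = 21L)
  expect_equal(sum(sfs$xi), sum(seg), tolerance = 1e-9)
  # accuracy against the known ancestral states
  truth_major_anc <- pol$major[seg] == sim$sites$ingroup[pol$site[seg]]
  acc <- mean(ifelse(truth_major_anc, pol$p_major_ancestral[seg],
                     1 - pol$p_major_ancestral[seg]))
  expect_gt(acc, 0.9)
  # class totals close to the generator's spectra
  expect_equal(rowSums(sfs$xi), rowSums(sim$sfs$xi), tolerance = 0.1)
})

test_that("incomplete ingroup samples violate the polarization contract", {
  sites <- tibble::tibble(
    site = 1L, major = "A", minor = "G",
    major_count = 5L, minor_count = 3L, o1 = "A", o2 = "A"
  )
  expect_error(fit_outgroup_model(sites, n = 10L), "complete ingroup")
})
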