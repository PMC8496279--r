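test_that("diversity summary matches hand values on minimal data", {
  # two sequences differing at 1 of 10 sites
  out <- diversity_summary(tibble::tibble(j = 1L), n = 2L, total_sites = 10)
  expect_equal(out$pi, 0.1)
  expect_equal(out$theta_w, 0.1)
  expect_equal(out$prop_singletons, 1)
  expect_error(diversity_summary(tibble::tibble(j = 1L), n = 1L, 10),
               "at least 2")
  expect_error(diversity_summary(tibble::tibble(j = 5L), n = 4L, 10),
               "1..n-1")
})

test_that("pi matches brute-force pairwise counting", {
  set.seed(7)
  n <- 8L
  L <- 40L
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  j_list <- integer(0)
  for (s in sample.int(L, 12L)) {
    jj <- sample.int(n - 1L, 1L)
    der <- setdiff(c("A", "C", "G", "T"), anc[s])[1]
    mat[sample.int(n, jj), s] <- der
    j_list <- c(j_list, jj)
  }
  brute <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    brute <- brute + sum(mat[a, ] != mat[b, ])
  }
  brute_pi <- brute / choose(n, 2) / L
  out <- diversity_summary(tibble::tibble(j = j_list), n = n,
                           total_sites = L)
  expect_equal(out$pi, brute_pi, tolerance = 1e-12)
})

test_that("singleton ratio reproduces the unfolded neutral expectation", {
  # sample of 69: neutral expectation 1/H_68; observed proportion 0.308
  H68 <- sum(1 / 1:68)
  expect_equal(round(0.308 * H68, 2), 1.48)
  # through the function: construct a spectrum with the right proportion
  S <- 1000L
  j <- c(rep(1L, 308L), rep(2L, S - 308L))
  out <- diversity_summary(tibble::tibble(j = j), n = 69L,
                           total_sites = 1e5)
  expect_equal(round(out$singleton_ratio, 2), 1.48)
})

test_that("Tajima's D tracks spectrum skew", {
  n <- 21L
  neutral_exp <- 1e4 / seq_len(n - 1L)
  to_j <- function(e) rep(seq_len(n - 1L), round(e))
  d_neutral <- diversity_summary(tibble::tibble(j = to_j(neutral_exp)),
                                 n = n, total_sites = 1e6)$tajima_d
  expect_equal(d_neutral, 0, tolerance = 0.05)
  skewed <- neutral_exp * c(3, rep(1, n - 2L)) # excess singletons
  d_skew <- diversity_summary(tibble::tibble(j = to_j(skewed)),
                              n = n, total_sites = 1e6)$tajima_d
  expect_lt(d_skew, -0.5)
})

test_that("mean DAF matches closed forms", {
  n <- 10L
  xi <- matrix(0, 3, n - 1L, dimnames = list(c("SW", "WS", "neu"), NULL))
  xi["SW", 1] <- 50 # all singletons
  xi["WS", ] <- 5 # uniform
  a_n <- sum(1 / seq_len(n - 1L))
  xi["neu", ] <- 1000 / seq_len(n - 1L) # neutral shape
  daf <- mean_daf(class_sfs(n, xi))
  expect_equal(daf$daf[daf$class == "SW"], 0.1)
  expect_equal(daf$daf[daf$class == "WS"], 0.5)
  expect_equal(daf$daf[daf$class == "neu"], (n - 1) / (n * a_n),
               tolerance = 1e-12)
})

test_that("closed-form equilibrium diversity agrees with Wright's density", {
  for (kappa in c(2, 3, 4)) {
    for (gamma in c(-2, -0.5, 0.5, 2)) {
      closed <- equilibrium_diversity(kappa, gamma)
      numeric_h <- equilibrium_diversity_wright(kappa, gamma, theta = 1e-5)
      expect_equal(numeric_h, closed, tolerance = 5e-4)
    }
  }
  # gamma -> 0 continuity
  expect_equal(equilibrium_diversity(3, 1e-10),
               equilibrium_diversity(3, 0), tolerance = 1e-6)
})

test_that("a strong directional force removes diversity", {
  # under symmetric mutation (kappa = 1), any directional force strictly
  # lowers equilibrium diversity; under biased mutation a weak opposing
  # force first rebalances composition and can raise diversity, so strict
  # monotonicity holds only beyond the rebalancing region -- verified
  # against the Wright-density integral, not just the closed form
  h_sym <- vapply(c(0, 0.5, 1, 2, 4), equilibrium_diversity,
                  numeric(1), kappa = 1)
  expect_true(all(diff(h_sym) < 0))
  h_sym_neg <- vapply(c(0, -0.5, -1, -2, -4), equilibrium_diversity,
                      numeric(1), kappa = 1)
  expect_true(all(diff(h_sym_neg) < 0))
  for (kappa in c(2, 4)) {
    gammas <- c(2, 4, 8, 16)
    h <- vapply(gammas, equilibrium_diversity, numeric(1), kappa = kappa)
    expect_true(all(diff(h) < 0))
    # the non-monotone hump near 0 for kappa > 1 is real, not a closed-form
    # artifact: the numeric Wright integral shows it too
    expect_gt(equilibrium_diversity_wright(kappa, 0.5, theta = 1e-5),
              equilibrium_diversity_wright(kappa, 0, theta = 1e-5))
  }
})

test_that("relative diversity prediction has the right invariances", {
  expect_equal(predict_relative_diversity(c(kappa = 3, gamma = 1.2),
                                          c(kappa = 3, gamma = 1.2)), 1)
  expect_equal(predict_relative_diversity(c(kappa = 2.5, gamma = 0),
                                          c(kappa = 2.5, gamma = 0)), 1)
  # ratio below 1 when a carries the much stronger force at equal kappa
  expect_lt(predict_relative_diversity(c(kappa = 3, gamma = 4),
                                       c(kappa = 3, gamma = 0.5)), 1)
})

test_that("the mutation-load arithmetic matches the consensus rate", {
  expect_equal(mutations_per_generation(5e-9, 1.4e8), 0.7)
})
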