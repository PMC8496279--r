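test_that("identical seed and config give bit-identical output", {
  cfg <- sim_config(gamma = 1, kappa = 3, n = 11L, n_introns = 300L,
                    theta_ws = 120, theta_sw = 120, theta_neu = 120,
                    seed = 77)
  expect_identical(simulate_class_sfs(cfg), simulate_class_sfs(cfg))
  s1 <- simulate_triplet_alignment(cfg)
  s2 <- simulate_triplet_alignment(cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$haplotypes, s2$haplotypes)
  expect_identical(s1$truth, s2$truth)
})

test_that("config validation rejects invalid parameters", {
  expect_error(sim_config(kappa = -1), "range")
  expect_error(sim_config(polarization_error = 0.5), "range")
  expect_error(sim_config(n = 1), ">= 2")
  expect_error(sim_config(distortion = c(1, -1), n = 3), "positive")
  expect_error(sim_config(gc_distribution = 1.2, n_introns = 2), "inside")
})

test_that("neutral simulation follows the 1/j law and distortion scales it", {
  n <- 11L
  cfg <- sim_config(gamma = 0, theta_ws = 1e5, theta_sw = 1e5,
                    theta_neu = 1e5, n = n, seed = 5)
  sfs <- simulate_class_sfs(cfg)
  j <- seq_len(n - 1L)
  for (cl in c("SW", "WS", "neu")) {
    ratio <- sfs$xi[cl, ] / sfs$xi[cl, 1L]
    # Poisson relative error at theta = 1e5 is ~ 1/sqrt(1e4) per entry
    expect_equal(ratio, 1 / j, tolerance = 0.05)
  }
  # multiplicative nuisance: constant r_j scales the expectation only
  cfg_r <- sim_config(gamma = 0, theta_ws = 1e5, theta_sw = 1e5,
                      theta_neu = 1e5, n = n,
                      distortion = rep(2, n - 1L), seed = 5)
  expect_equal(attr(simulate_class_sfs(cfg_r), "expected"),
               2 * attr(simulate_class_sfs(cfg), "expected"),
               tolerance = 1e-12)
})

test_that("W>S mutations have higher mean DAF than S>W under a GC force", {
  n <- 21L
  cfg <- sim_config(gamma = 2, kappa = 3, theta_ws = 2e4, theta_sw = 2e4,
                    theta_neu = 2e4, n = n, seed = 8)
  daf <- mean_daf(simulate_class_sfs(cfg))
  d_ws <- daf$daf[daf$class == "WS"]
  d_sw <- daf$daf[daf$class == "SW"]
  expect_gt(d_ws, d_sw)
  # gap matches the diffusion prediction computed from the expected SFS
  j <- seq_len(n - 1L)
  daf_pred <- function(g) {
    e <- expected_sfs(g, 1, n)
    sum(j * e) / (n * sum(e))
  }
  expect_equal(d_ws - d_sw, daf_pred(2) - daf_pred(-2), tolerance = 0.01)
})

test_that("Wright-Fisher forward simulation agrees with the diffusion SFS", {
  n <- 10L
  M <- 500L
  for (gamma in c(-2, 0, 2)) {
    batches <- vapply(1:4, function(b) {
      suppressWarnings(
        wright_fisher_oracle(gamma, n = n, pop_size = M, reps = 6e4,
                             seed = 100 * b + gamma, theta = 1)$count
      )
    }, numeric(n - 1L))
    est <- rowMeans(batches)
    se <- apply(batches, 1L, stats::sd) / sqrt(ncol(batches))
    analytic <- expected_sfs(gamma, 1, n)
    # each entry within 4 batch standard errors plus discretization slack
    expect_true(all(abs(est - analytic) < 4 * se + 0.01 * analytic),
                info = paste("gamma =", gamma))
    # KS-style distance between normalized spectra
    D <- max(abs(cumsum(est) / sum(est) - cumsum(analytic) / sum(analytic)))
    expect_lt(D, 0.02)
  }
})

test_that("triplet simulation respects branch lengths and equilibrium GC", {
  # zero branch lengths: all species identical, no substitutions
  cfg0 <- sim_config(theta_ws = 0, theta_sw = 0, theta_neu = 0, n = 4L,
                     n_introns = 40L,
                     branch_lengths = c(ingroup = 0, sister = 0,
                                        outgroup = 0), seed = 2)
  sim0 <- simulate_triplet_alignment(cfg0)
  expect_identical(sim0$sites$ingroup, sim0$sites$ancestor)
  expect_identical(sim0$sites$sister, sim0$sites$ancestor)
  expect_identical(sim0$sites$outgroup, sim0$sites$ancestor)
  expect_equal(sum(sim0$truth$n_total), 0)

  # symmetric stationary model: GC drifts to 0.5
  cfg5 <- sim_config(kappa = 1, gamma = 0, theta_ws = 0, theta_sw = 0,
                     theta_neu = 0, n = 4L, n_introns = 800L, seed = 3,
                     branch_lengths = c(ingroup = 3, sister = 0,
                                        outgroup = 0))
  sim5 <- simulate_triplet_alignment(cfg5)
  expect_equal(mean(sim5$sites$ingroup %in% c("C", "G")), 0.5,
               tolerance = 0.02)

  # kappa = 3, gamma = 0 at stationarity: equilibrium GC = 1/(1+kappa)
  cfg25 <- sim_config(kappa = 3, gamma = 0, theta_ws = 0, theta_sw = 0,
                      theta_neu = 0, n = 4L, n_introns = 800L, seed = 4,
                      branch_lengths = c(ingroup = 3, sister = 0,
                                         outgroup = 0))
  sim25 <- simulate_triplet_alignment(cfg25)
  expect_equal(mean(sim25$sites$ingroup %in% c("C", "G")), 0.25,
               tolerance = 0.02)
})

test_that("truth tables conserve labelled counts and polymorphism replaces fixation", {
  cfg <- sim_config(gamma = 0.5, kappa = 3, theta_ws = 150, theta_sw = 150,
                    theta_neu = 150, n = 9L, n_introns = 400L, seed = 6)
  sim <- simulate_triplet_alignment(cfg)
  expect_true(all(sim$truth$n_sw + sim$truth$n_ws + sim$truth$n_neu ==
                    sim$truth$n_total))
  # polymorphic sites are never fixed differences: the ingroup reference
  # matches the ancestor at every overlaid site
  poly <- sim$polymorphisms
  expect_gt(nrow(poly), 0)
  expect_identical(sim$sites$ingroup[poly$site],
                   sim$sites$ancestor[poly$site])
  # each polymorphic site has exactly the requested derived count
  for (i in sample.int(nrow(poly), 25L)) {
    col <- sim$haplotypes[, poly$site[i]]
    expect_equal(sum(col == poly$der[i]), poly$j[i])
    expect_equal(sum(col == poly$anc[i]), cfg$n - poly$j[i])
  }
  # realized polymorphism counts match the drawn SFS per class
  tab <- table(poly$class)
  expect_equal(as.numeric(tab[c("SW", "WS", "neu")]),
               unname(rowSums(sim$sfs$xi)[c("SW", "WS", "neu")]))
})

test_that("FASTA export round-trips sequences and truth tables", {
  cfg <- sim_config(theta_ws = 6, theta_sw = 6, theta_neu = 6, n = 5L,
                    n_introns = 6L, seed = 12)
  sim <- simulate_triplet_alignment(cfg)
  dir <- withr::local_tempdir()
  write_triplet_fasta(sim, dir)
  files <- list.files(dir, pattern = "\\.fa$")
  expect_length(files, 6L)
  aln <- Biostrings::readDNAStringSet(file.path(dir, files[1]))
  expect_length(aln, cfg$n + 2L)
  cols <- sim$sites$intron_id == 1L
  expect_equal(as.character(aln[["sister_ref"]]),
               paste(sim$sites$sister[cols], collapse = ""))
  expect_equal(as.character(aln[["sample_01"]]),
               paste(sim$haplotypes[1, cols], collapse = ""))
  truth <- readr::read_tsv(file.path(dir, "truth_substitutions.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(sim$truth))
})
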