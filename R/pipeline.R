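# End-to-end pipeline driver: per-bin polymorphism and divergence
# analyses, with deterministic per-stage seeding, structured attrition
# logging, and a machine-readable summary.

#' Pipeline configuration
#'
#' Validates and freezes the configuration of [run_pipeline()].  Two modes
#' are supported.  In `"synthetic"` mode the pipeline generates its own
#' per-bin inputs from [sim_config()] parameters with a (possibly
#' bin-specific) planted `gamma`, then runs the full chain: polarization,
#' class SFSs, diversity and DAF summaries, directional-force model fits
#' with likelihood ratio tests, and divergence counting.  In `"files"`
#' mode the annotation stages (extract, intersect, filter, bin) are run on
#' user-supplied GFF3/FASTA/WGA-BED inputs and per-bin site tables are
#' written; downstream stages then run on any bins that carry polymorphism
#' columns.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param out_dir Output directory.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param k Number of GC bins (default 5).
#' @param n_boot Bootstrap replicates for CIs (default 1000).
#' @param gamma_by_bin In synthetic mode, vector of planted `gamma` values
#'   (length `k`).
#' @param gc_by_bin Optional per-bin target GC fractions; default spreads
#'   bins over 0.16..0.40, mirroring the empirical SI GC range.
#' @param sim Base arguments passed to [sim_config()] for every bin
#'   (synthetic mode).
#' @param models Model tags fitted per bin (default `c("M0", "M1")`).
#' @param divergence_runs Optimization runs for [fit_nonstationary()]
#'   (default 3 in the pipeline; raise for final analyses).
#' @param drop_polymorphic Remove sites segregating in the focal sample
#'   before divergence counting.
#' @param make_plots Write ggplot figures alongside the tables.
#' @param files Named list of input paths for `"files"` mode: `gff_a`,
#'   `fasta_a`, `gff_b`, `fasta_b`, `wga`, plus optional filter inputs
#'   (`autosomes_a`, `exclude_a`, ...) forwarded to
#'   [apply_site_filters()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            out_dir = tempfile("sispec_run_"),
                            seed = 1L, k = 5L, n_boot = 1000L,
                            gamma_by_bin = c(0, 0.5, 1, 1.5, 2.1),
                            gc_by_bin = NULL,
                            sim = list(), models = c("M0", "M1"),
                            divergence_runs = 3L,
                            drop_polymorphic = FALSE,
                            make_plots = FALSE,
                            files = list()) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (mode == "synthetic") {
    gamma_by_bin <- rep_len(gamma_by_bin, k)
    gc_by_bin <- gc_by_bin %||% seq(0.16, 0.40, length.out = k)
  }
  structure(
    list(mode = mode, out_dir = out_dir, seed = as.integer(seed), k = k,
         n_boot = as.integer(n_boot), gamma_by_bin = gamma_by_bin,
         gc_by_bin = gc_by_bin, sim = sim, models = models,
         divergence_runs = as.integer(divergence_runs),
         drop_polymorphic = isTRUE(drop_polymorphic),
         make_plots = isTRUE(make_plots), files = files),
    class = "pipeline_config"
  )
}

pipeline_log <- function(log_path, stage, message_text) {
  line <- sprintf("[%s] %s", stage, message_text)
  cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}

run_bin_synthetic <- function(config, bin) {
  sim_args <- config$sim
  sim_args$gamma <- config$gamma_by_bin[bin]
  sim_args$seed <- derive_seed(config$seed + 1000L * bin, "pipeline")
  g_bin <- config$gc_by_bin[bin]
  sim_args$gc_distribution <- sim_args$gc_distribution %||% g_bin
  # class mutation inputs scale with the number of source sites: the S>W
  # input is kappa times the W>S per-site rate times the S/W site ratio
  kappa_bin <- sim_args$kappa %||% formals(sim_config)$kappa
  theta_ws_bin <- sim_args$theta_ws %||% formals(sim_config)$theta_ws
  sim_args$theta_sw <- sim_args$theta_sw %||%
    (theta_ws_bin * kappa_bin * g_bin / (1 - g_bin))
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_triplet_alignment(cfg)

  sites <- triplet_sites(sim)
  om <- fit_outgroup_model(sites, n = cfg$n, n_restarts = 3L,
                           seed = derive_seed(config$seed + bin, "polarize"))
  pol <- polarize(sites, om)
  sfs <- build_class_sfs(pol, n = cfg$n)

  seg <- pol |> filter(!is.na(.data$minor))
  j_der <- round(ifelse(seg$p_major_ancestral >= 0.5,
                        cfg$n - seg$major_count, seg$major_count))
  div <- diversity_summary(tibble(j = pmin(pmax(j_der, 1), cfg$n - 1L)),
                           n = cfg$n, total_sites = nrow(sites))
  daf <- mean_daf(sfs)

  fits <- purrr::map(setNames(config$models, config$models), function(m) {
    fit_sfs_model(sfs, model = m, n_restarts = 5L,
                  seed = derive_seed(config$seed + bin, "fit"))
  })
  lrt <- if (all(c("M0", "M1") %in% names(fits))) {
    likelihood_ratio_test(fits$M0, fits$M1)
  } else {
    tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  }

  div_sites <- sim$sites
  if (config$drop_polymorphic && nrow(sim$polymorphisms) > 0) {
    div_sites <- div_sites[-sim$polymorphisms$site, , drop = FALSE]
  }
  nsm <- fit_nonstationary(div_sites, n_runs = config$divergence_runs,
                           seed = derive_seed(config$seed + bin, "divergence"))
  subs <- expected_substitution_counts(nsm, lineages = "ingroup")
  chi2 <- equilibrium_chi2(subs$n_ws[1], subs$n_sw[1])

  m1 <- fits[["M1"]] %||% fits[[length(fits)]]
  list(
    sim = sim, sfs = sfs, fits = fits,
    row = tibble(
      bin = bin, strategy = "mean", population = "synthetic",
      target_gc = config$gc_by_bin[bin],
      gamma_true = config$gamma_by_bin[bin],
      gamma_hat = m1$gamma, kappa_hat = m1$kappa,
      loglik_M1 = m1$loglik,
      lrt_stat = lrt$statistic, lrt_p = lrt$p_value,
      pi = div$pi, theta_w = div$theta_w, tajima_d = div$tajima_d,
      prop_singletons = div$prop_singletons,
      daf_sw = daf$daf[daf$class == "SW"],
      daf_ws = daf$daf[daf$class == "WS"],
      daf_neu = daf$daf[daf$class == "neu"],
      n_sw = subs$n_sw[1], n_ws = subs$n_ws[1],
      R = subs$R[1], ancestral_gc = subs$ancestral_gc[1],
      equilibrium_chi2 = chi2$statistic, equilibrium_p = chi2$p_value
    )
  )
}

#' Run the per-bin analysis pipeline
#'
#' Executes the configured stages per GC bin and writes per-bin tables
#' (TSV), a machine-readable JSON summary, a structured log with
#' per-filter attrition counts, and (optionally) figures.  All randomness
#' flows from the single master seed, split per stage and bin, so the same
#' configuration and seed give byte-identical JSON output.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the per-bin results tibble (also written to
#'   `bin_results.tsv` / `summary.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_path)
  cfg_echo <- unclass(config)
  cfg_echo$files <- NULL
  jsonlite::write_json(cfg_echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (config$mode == "files") {
    return(invisible(run_pipeline_files(config, log_path)))
  }

  results <- purrr::map(seq_len(config$k), function(b) {
    pipeline_log(log_path, sprintf("bin%02d", b), "simulate + analyse")
    run_bin_synthetic(config, b)
  })
  rows <- purrr::map_dfr(results, "row")
  readr::write_tsv(rows, file.path(config$out_dir, "bin_results.tsv"))
  jsonlite::write_json(
    list(seed = config$seed, k = config$k, bins = rows),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  if (config$make_plots) {
    for (p in c("gamma", "R")) {
      gg <- plot_bin_estimates(rows, param = if (p == "gamma") "gamma_hat"
                               else "R")
      ggplot2::ggsave(file.path(config$out_dir, paste0(p, "_by_bin.png")),
                      gg, width = 5, height = 4, dpi = 150)
    }
  }
  pipeline_log(log_path, "done", sprintf("%d bins written", config$k))
  invisible(rows)
}

run_pipeline_files <- function(config, log_path) {
  f <- config$files
  needed <- c("gff_a", "fasta_a", "gff_b", "fasta_b", "wga")
  if (!all(needed %in% names(f))) {
    abort(sprintf("files mode needs inputs: %s.",
                  paste(setdiff(needed, names(f)), collapse = ", ")))
  }
  si_a <- extract_short_introns(f$gff_a, f$fasta_a)
  pipeline_log(log_path, "extract", sprintf("species a: %d SI regions",
                                            nrow(si_a)))
  si_b <- extract_short_introns(f$gff_b, f$fasta_b)
  pipeline_log(log_path, "extract", sprintf("species b: %d SI regions",
                                            nrow(si_b)))
  wga <- read_wga_bed(f$wga)
  sites <- intersect_homologous_sites(si_a, si_b, wga)
  pipeline_log(log_path, "intersect",
               sprintf("%d homologous SI sites (%d columns skipped)",
                       nrow(sites), attr(sites, "n_skipped")))
  filter_args <- f[intersect(names(f),
                             c("autosomes_a", "autosomes_b", "exclude_a",
                               "exclude_b", "qual", "qual_threshold",
                               "mode"))]
  sites <- do.call(apply_site_filters, c(list(sites), filter_args))
  att <- attr(sites, "attrition")
  if (!is.null(att)) {
    for (i in seq_len(nrow(att))) {
      pipeline_log(log_path, "filter",
                   sprintf("%s removed %d", att$filter[i], att$removed[i]))
    }
  }
  homologs <- sites |>
    group_by(intron_id = .data$intron_id_a) |>
    summarise(n_sites = dplyr::n(), .groups = "drop") |>
    left_join(si_a |> select("intron_id", gc_a = "gc"), by = "intron_id")
  gc_b_tbl <- si_b |> select(intron_id_b = "intron_id", gc_b = "gc")
  pair_gc <- sites |>
    dplyr::distinct(.data$intron_id_a, .data$intron_id_b) |>
    left_join(si_a |> select(intron_id_a = "intron_id", gc_a = "gc"),
              by = "intron_id_a") |>
    left_join(gc_b_tbl, by = "intron_id_b") |>
    mutate(gc_mean = (.data$gc_a + .data$gc_b) / 2,
           intron_id = .data$intron_id_a)
  binned <- assign_gc_bins(pair_gc, gc = "gc_mean", k = config$k)
  readr::write_tsv(binned, file.path(config$out_dir, "intron_bins.tsv"))
  sites_out <- sites |>
    left_join(binned |> select("intron_id_a", "bin"), by = "intron_id_a")
  readr::write_tsv(sites_out, file.path(config$out_dir, "si_sites.tsv"))
  pipeline_log(log_path, "bin", sprintf("%d introns into %d bins",
                                        nrow(binned), config$k))
  sites_out
}
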