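# GC content, quintile binning, and intron-level bootstrap.

#' GC fraction of sequences
#'
#' `(#G + #C) / (#A + #C + #G + #T)`, ignoring `N`s; case-insensitive.
#' The "mean" binning basis for a homologous intron pair is simply the
#' arithmetic mean of the two species' values (e.g. `rowMeans()` over the
#' two GC columns).
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of GC fractions; an all-`N` (or empty) sequence
#'   is an error.
#' @examples
#' compute_gc(c("GGCCA", "AATT"))
#' @export
compute_gc <- function(seq) {
  up <- toupper(seq)
  counts <- vapply(c("G", "C", "A", "T"), function(b) {
    stringr::str_count(up, stringr::fixed(b))
  }, numeric(length(seq)))
  counts <- matrix(counts, ncol = 4)
  informative <- rowSums(counts)
  if (any(informative == 0)) {
    abort("GC content undefined: sequence with no A/C/G/T bases.")
  }
  (counts[, 1] + counts[, 2]) / informative
}

#' Assign introns to equal-occupancy GC bins
#'
#' Orders introns by increasing GC (stable sort; ties broken by
#' `intron_id` for determinism) and splits them into `k` contiguous groups
#' of size `floor(N / k)`, with the remainder appended to the final
#' (highest-GC) bin -- so 9327 introns give four bins of 1865 and a final
#' bin of 1867.
#'
#' @param introns Tibble with one row per intron, including an `intron_id`
#'   column and the GC column named by `gc`.
#' @param gc Name of the GC column to bin on: the per-species value for
#'   "species" binning or the mean of the two homologs for "mean" binning.
#' @param k Number of bins (default 5).
#' @return The input tibble with an integer `bin` column (1 = lowest GC).
#' @export
assign_gc_bins <- function(introns, gc = "gc_mean", k = 5L) {
  k <- as.integer(k)
  if (k <= 0L) abort("`k` must be a positive integer.")
  if (nrow(introns) < k) abort("Fewer introns than bins.")
  if (!gc %in% names(introns)) {
    abort(sprintf("Column `%s` not found.", gc))
  }
  ord <- order(introns[[gc]], introns$intron_id)
  N <- nrow(introns)
  base <- N %/% k
  sizes <- c(rep(base, k - 1L), N - base * (k - 1L))
  bin_sorted <- rep(seq_len(k), times = sizes)
  introns$bin <- integer(N)
  introns$bin[ord] <- bin_sorted
  introns
}

#' Summary of a bin assignment
#'
#' @param introns Output of [assign_gc_bins()].
#' @inheritParams assign_gc_bins
#' @return One row per bin: size and GC range.
#' @export
bin_summary <- function(introns, gc = "gc_mean") {
  introns |>
    group_by(bin = .data$bin) |>
    summarise(
      n = dplyr::n(),
      gc_min = min(.data[[gc]]),
      gc_max = max(.data[[gc]]),
      gc_mean = mean(.data[[gc]]),
      .groups = "drop"
    ) |>
    arrange(.data$bin)
}

#' Intron-level bootstrap percentile confidence interval
#'
#' Resamples whole introns (rows of `data`) with replacement to the
#' original count `n_boot` times, recomputes `statistic` on each
#' resample, and returns the 2.5% and 97.5% quantiles of the resulting
#' distribution as the 95% CI.  Replicates on which the statistic is
#' undefined (`NA` or an error, e.g. an empty mutation class) are skipped
#' and counted; more than 10% skipped is an error.
#'
#' @param data Tibble whose rows are the resampling units (introns).
#' @param statistic Function taking a resampled tibble and returning a
#'   single number.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `point`, `ci_low`, `ci_high`, `n_boot`,
#'   `n_skipped`.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000L, seed = NULL,
                         level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  point <- statistic(data)
  check_number(point, "statistic(data)")
  N <- nrow(data)
  reps <- vapply(seq_len(n_boot), function(b) {
    res <- tryCatch(statistic(data[sample.int(N, N, replace = TRUE), ,
                                   drop = FALSE]),
                    error = function(e) NA_real_)
    if (length(res) != 1L) NA_real_ else as.numeric(res)
  }, numeric(1))
  n_skipped <- sum(is.na(reps))
  if (n_skipped > 0.1 * n_boot) {
    abort(sprintf("Statistic undefined on %d of %d bootstrap replicates.",
                  n_skipped, n_boot))
  }
  alpha <- (1 - level) / 2
  qs <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble(point = point, ci_low = qs[1], ci_high = qs[2],
         n_boot = as.integer(n_boot), n_skipped = as.integer(n_skipped))
}
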