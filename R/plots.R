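# ggplot2 displays for the main result types.

#' Plot a class-specific unfolded SFS
#'
#' Bars of derived-allele counts per frequency class, one panel colour per
#' mutation class.
#'
#' @param object A [class_sfs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_sfs <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$j, y = .data$count,
                                 fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "derived allele count j", y = "sites",
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' Observed versus fitted spectra for a model fit
#'
#' @param object A `gbgc_fit`; the observed SFS must be refittable from
#'   the stored parameters, so the observed spectrum is passed explicitly.
#' @param sfs The [class_sfs()] the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gbgc_fit <- function(object, sfs, ...) {
  m <- sfs_cell_means(object$gamma, object$theta,
                      object$r, object$eps %||% 0, object$n)
  obs <- as_tibble(sfs) |> mutate(kind = "observed")
  fit <- tidyr::expand_grid(class = SFS_CLASSES,
                            j = seq_len(object$n - 1L)) |>
    mutate(count = purrr::map2_dbl(.data$class, .data$j, \(c, j) m[c, j]),
           kind = "fitted")
  bind_rows(obs, fit) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$j, y = .data$count,
                                 colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = \(d) d[d$kind == "fitted", ]) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "derived allele count j", y = "sites") +
    ggplot2::theme_minimal()
}

#' Per-bin estimates with confidence intervals
#'
#' Point estimates of a chosen per-bin quantity (e.g. `gamma_hat`,
#' `kappa_hat`, `R`) against GC bin, with error bars when columns
#' `<param>_low` / `<param>_high` are present.
#'
#' @param results Per-bin results tibble (from [run_pipeline()] or built
#'   manually with a `bin` column).
#' @param param Name of the column to plot.
#' @return A ggplot object.
#' @export
plot_bin_estimates <- function(results, param = "gamma_hat") {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = factor(.data$bin),
                                    y = .data[[param]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "GC bin (1 = lowest)", y = param) +
    ggplot2::theme_minimal()
  lo <- paste0(param, "_low")
  hi <- paste0(param, "_high")
  if (all(c(lo, hi) %in% names(results))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]), width = 0.2
    )
  }
  p
}

#' Mean derived allele frequency per class across bins
#'
#' @param daf_by_bin Tibble with columns `bin`, `class`, `daf` (and
#'   optionally `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_daf <- function(daf_by_bin) {
  p <- ggplot2::ggplot(daf_by_bin,
                       ggplot2::aes(x = factor(.data$bin), y = .data$daf,
                                    colour = .data$class,
                                    group = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "GC bin (1 = lowest)", y = "mean DAF") +
    ggplot2::theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(daf_by_bin))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
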