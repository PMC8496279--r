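# Container for class-specific unfolded site frequency spectra.

#' Build a class-specific unfolded SFS object
#'
#' Bundles the three unfolded site frequency spectra (S>W, W>S, and neutral
#' W>W / S>S changes) for a haploid sample of size `n`, together with the
#' surveyed numbers of monomorphic-or-ancestral weak (`L_W`) and strong
#' (`L_S`) sites.  Entries may be fractional, since probability-weighted
#' polarization distributes each segregating site across the two possible
#' orientations.
#'
#' @param n Haploid sample size.
#' @param xi Numeric matrix of expected derived-allele counts with rows
#'   `"SW"`, `"WS"`, `"neu"` and `n - 1` columns (derived counts
#'   `j = 1..n-1`).
#' @param L_W,L_S Surveyed counts of weak (A/T) and strong (G/C) sites that
#'   are monomorphic or ancestral; used to convert class mutation inputs
#'   into the per-site rate ratio kappa.
#' @return An object of class `class_sfs`.
#' @export
class_sfs <- function(n, xi, L_W = NA_real_, L_S = NA_real_) {
  n <- as.integer(n)
  if (n < 2L) abort("`n` must be at least 2.")
  if (!is.matrix(xi) || ncol(xi) != n - 1L) {
    abort("`xi` must be a matrix with n - 1 columns.")
  }
  if (is.null(rownames(xi)) || !setequal(rownames(xi), SFS_CLASSES)) {
    abort('`xi` must have rownames "SW", "WS", "neu".')
  }
  xi <- xi[SFS_CLASSES, , drop = FALSE]
  if (any(xi < 0)) abort("SFS entries must be non-negative.")
  structure(
    list(n = n, xi = xi, L_W = L_W, L_S = L_S),
    class = "class_sfs"
  )
}

#' @export
print.class_sfs <- function(x, ...) {
  cat(sprintf(
    "Class-specific unfolded SFS: n = %d, %.1f segregating sites\n",
    x$n, sum(x$xi)
  ))
  cat(sprintf(
    "  S>W %.1f | W>S %.1f | neutral %.1f | L_W %s | L_S %s\n",
    sum(x$xi["SW", ]), sum(x$xi["WS", ]), sum(x$xi["neu", ]),
    format(x$L_W), format(x$L_S)
  ))
  invisible(x)
}

#' @export
as_tibble.class_sfs <- function(x, ...) {
  tidyr::expand_grid(class = SFS_CLASSES, j = seq_len(x$n - 1L)) |>
    mutate(count = purrr::map2_dbl(.data$class, .data$j, \(c, j) x$xi[c, j]))
}

#' Assemble a class SFS from a tidy table of counts
#'
#' Inverse of `as_tibble()` on a [class_sfs()]: takes a data frame with
#' columns `class` (`"SW"`, `"WS"`, `"neu"`), `j`, and `count`.
#'
#' @param data Data frame of per-class, per-frequency counts.
#' @inheritParams class_sfs
#' @return A `class_sfs` object.
#' @export
as_class_sfs <- function(data, n, L_W = NA_real_, L_S = NA_real_) {
  stopifnot(all(c("class", "j", "count") %in% names(data)))
  xi <- matrix(0, nrow = 3L, ncol = n - 1L, dimnames = list(SFS_CLASSES, NULL))
  keep <- data$j >= 1 & data$j <= n - 1
  data <- data[keep, , drop = FALSE]
  for (i in seq_len(nrow(data))) {
    xi[data$class[i], data$j[i]] <- xi[data$class[i], data$j[i]] + data$count[i]
  }
  class_sfs(n, xi, L_W = L_W, L_S = L_S)
}
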