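# Internal helpers shared across modules.

# Strong (G/C) and weak (A/T) allele coding used throughout.
STRONG <- c("C", "G")
WEAK <- c("A", "T")
BASES <- c("A", "C", "G", "T")

is_strong <- function(x) x %in% STRONG

# Mutation class of an ancestral -> derived change.
mutation_class <- function(anc, der) {
  s_anc <- is_strong(anc)
  s_der <- is_strong(der)
  dplyr::case_when(
    s_anc & !s_der ~ "SW",
    !s_anc & s_der ~ "WS",
    TRUE ~ "neu"
  )
}

SFS_CLASSES <- c("SW", "WS", "neu")

# Cached Gauss-Legendre rule on [0, 1].
.gl_env <- new.env(parent = emptyenv())

gl_rule <- function(order = 64L) {
  key <- as.character(order)
  if (is.null(.gl_env[[key]])) {
    # Golub-Welsch: nodes/weights from the Jacobi matrix of the Legendre
    # recurrence, then affine map [-1, 1] -> [0, 1].
    k <- seq_len(order - 1L)
    b <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, order, order)
    J[cbind(k, k + 1L)] <- b
    J[cbind(k + 1L, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    x <- (e$values + 1) / 2
    w <- (2 * e$vectors[1L, ]^2) / 2
    o <- order(x)
    .gl_env[[key]] <- list(x = x[o], w = w[o])
  }
  .gl_env[[key]]
}

# Harmonic number H_k = sum_{i=1}^k 1/i.
harmonic <- function(k) {
  if (k < 1) return(0)
  sum(1 / seq_len(k))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  up_ok <- if (strict_upper) x < upper else x <= upper
  if (!low_ok || !up_ok) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x))
  }
  invisible(x)
}

# Deterministic per-stage seed derived from a master seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    sfs = 11L, wf = 23L, triplet = 37L, bootstrap = 53L, polarize = 71L,
    fit = 89L, divergence = 101L, pipeline = 113L
  )
  off <- offsets[[stage]] %||% 127L
  as.integer((as.numeric(seed) * 2654435.0 + off * 97.0) %% 2147483629) + 1L
}
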