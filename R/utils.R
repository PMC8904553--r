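#' @keywords internal
"_PACKAGE"

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministically expand one master seed into n child seeds (< 2^31).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Composite Simpson integration of sampled data
#'
#' Integrates `y` over `x` with the composite Simpson rule. The samples must
#' lie on a uniform grid with an odd number of points (an even number of
#' panels); [resample_to_common_grid()] produces such a grid.
#'
#' @param x Strictly increasing, uniformly spaced abscissae (odd length >= 3).
#' @param y Ordinates, same length as `x`.
#' @return The integral as a scalar.
#' @export
simpson_integral <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("`x` and `y` must have the same length", call. = FALSE)
  if (n < 3L || n %% 2L == 0L) {
    stop("composite Simpson needs an odd number of points (>= 3)", call. = FALSE)
  }
  h <- diff(x)
  if (any(abs(h - h[1L]) > 1e-8 * abs(h[1L]))) {
    stop("composite Simpson needs a uniform grid", call. = FALSE)
  }
  idx <- seq_len(n)
  h[1L] / 3 * (y[1L] + y[n] +
    4 * sum(y[idx %% 2L == 0L]) +
    2 * sum(y[idx %% 2L == 1L & idx > 1L & idx < n]))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
}
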