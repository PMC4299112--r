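# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rgamma fft sd var toeplitz
#' @importFrom utils write.table read.table write.csv head tail
NULL

l2norm <- function(x) sqrt(sum(x^2))

#' Soft-thresholding operator
#' @param x numeric vector.
#' @param t threshold (>= 0).
#' @return `sign(x) * pmax(|x| - t, 0)`.
#' @keywords internal
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Stop with a formatted message; keeps call out of the error for cleaner tests.
abort <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) abort("%s contains non-finite values", what)
  invisible(x)
}

# Derive a reproducible sub-seed from a base seed and a stream index.
# Kept strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 10007 + stream * 7919) %% 2147483647)
}

#' Orthonormal real Fourier basis
#'
#' Returns the N x N orthogonal matrix whose rows are the constant vector,
#' paired cosine/sine atoms at increasing frequency, and (for even N) the
#' Nyquist alternation. `F %*% x` is the real spectrum of `x`; `t(F)` is the
#' synthesis operator. This is the real embedding of the unitary DFT used by
#' the l1-l1 program so that all solver arithmetic stays real.
#'
#' @param n segment length (>= 2).
#' @return an `n x n` orthogonal matrix (`F %*% t(F) = I`).
#' @export
fourier_basis <- function(n) {
  if (n < 2) abort("fourier_basis requires n >= 2")
  t_idx <- 0:(n - 1)
  rows <- list(rep(1 / sqrt(n), n))
  kmax <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  for (k in seq_len(kmax)) {
    rows[[length(rows) + 1]] <- sqrt(2 / n) * cos(2 * pi * k * t_idx / n)
    rows[[length(rows) + 1]] <- sqrt(2 / n) * sin(2 * pi * k * t_idx / n)
  }
  if (n %% 2 == 0) rows[[length(rows) + 1]] <- cos(pi * t_idx) / sqrt(n)
  do.call(rbind, rows)
}

#' Unitary complex DFT matrix
#'
#' @param n dimension.
#' @return complex `n x n` matrix with entries `exp(-2i*pi*j*k/n)/sqrt(n)`.
#' @export
dft_matrix <- function(n) {
  jk <- outer(0:(n - 1), 0:(n - 1))
  exp(-2i * pi * jk / n) / sqrt(n)
}

#' Orthonormal DCT-II basis
#'
#' Used to initialise the square dictionary in sensing-dictionary selection
#' when fewer training signals than atoms are available.
#'
#' @param n dimension.
#' @return `n x n` orthogonal matrix; columns are DCT atoms.
#' @export
dct_basis <- function(n) {
  k <- 0:(n - 1)
  B <- sqrt(2 / n) * cos(pi * outer(2 * k + 1, k) / (2 * n))
  B[, 1] <- 1 / sqrt(n)
  B
}
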