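# Random sensing matrices, suitability checks (mutual coherence, restricted
# isometry surrogate, measurement-count bound), the analog random-demodulator
# front end, and measurement generation (Algorithm I of the pipeline).

MATRIX_FAMILIES <- c("bernoulli", "gaussian", "binary_toeplitz", "rd_structured")

new_sensing_matrix <- function(entries, family, seed, column_normalized,
                               selected_rows = NULL, square = NULL) {
  structure(list(entries = entries, family = family,
                 m = nrow(entries), n = ncol(entries), seed = seed,
                 column_normalized = column_normalized,
                 selected_rows = selected_rows, square = square),
            class = "sensing_matrix")
}

#' @export
print.sensing_matrix <- function(x, ...) {
  cat(sprintf("<sensing_matrix> %d x %d, family=%s, seed=%s\n",
              x$m, x$n, x$family, format(x$seed)))
  invisible(x)
}

as_operator <- function(phi) {
  if (inherits(phi, "sensing_matrix")) phi$entries
  else if (is.matrix(phi)) phi
  else abort("expected a sensing_matrix or a plain matrix")
}

#' Build a random sensing matrix
#'
#' Families:
#' * `bernoulli` — i.i.d. entries of +/- 1/sqrt(M); every column has exactly
#'   unit l2 norm.
#' * `gaussian` — i.i.d. Normal(0, 1/M).
#' * `binary_toeplitz` — a +/-1 Toeplitz-structured N x N matrix (first row
#'   and first column drawn i.i.d., constant along diagonals), from which M
#'   rows are selected uniformly at random, scaled by 1/sqrt(M). The +/-1
#'   alphabet matches the chipping sequence of the analog front end. The
#'   unscaled pre-selection square matrix is retained in `$square`.
#'
#' @param family one of `"bernoulli"`, `"gaussian"`, `"binary_toeplitz"`.
#' @param m number of measurements, `1 <= m <= n`.
#' @param n signal length.
#' @param seed integer seed; the draw is reproducible.
#' @return a `sensing_matrix`.
#' @export
make_matrix <- function(family = c("bernoulli", "gaussian", "binary_toeplitz"),
                        m, n, seed = 1) {
  family <- match.arg(family)
  if (m > n) abort("m must not exceed n (got %d > %d)", m, n)
  if (m < 1) abort("m must be >= 1")
  withr::with_seed(seed, {
    if (family == "bernoulli") {
      ent <- matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n) / sqrt(m)
      new_sensing_matrix(ent, family, seed, column_normalized = TRUE)
    } else if (family == "gaussian") {
      ent <- matrix(rnorm(m * n, sd = 1 / sqrt(m)), m, n)
      new_sensing_matrix(ent, family, seed, column_normalized = FALSE)
    } else {
      first_col <- sample(c(-1, 1), n, replace = TRUE)
      first_row <- c(first_col[1], sample(c(-1, 1), n - 1, replace = TRUE))
      # T[i, j] = v[i - j + n] with v = (reversed row tail, column)
      v <- c(rev(first_row[-1]), first_col)
      square <- matrix(v[outer(seq_len(n), seq_len(n), function(i, j) i - j + n)], n, n)
      rows <- sort(sample.int(n, m))
      new_sensing_matrix(square[rows, , drop = FALSE] / sqrt(m), family, seed,
                         column_normalized = TRUE, selected_rows = rows,
                         square = square)
    }
  })
}

#' Mutual coherence between a sensing matrix and a sparsity basis
#'
#' Computes `mu = sqrt(N) * max |<phi_i, psi_j>|` over unit-normalised rows
#' of the sensing operator and columns of the (possibly complex) basis. For
#' orthonormal pairs, `1 <= mu <= sqrt(N)`; low values favour recovery.
#'
#' @param phi a `sensing_matrix` or an M x N matrix (rows are measurement
#'   vectors).
#' @param psi an N x N sparsity basis (columns are atoms); may be complex.
#' @return the scalar coherence `mu`.
#' @export
coherence <- function(phi, psi) {
  A <- as_operator(phi)
  n <- ncol(A)
  if (nrow(psi) != n) abort("dimension mismatch: phi has %d columns, psi %d rows", n, nrow(psi))
  rn <- sqrt(rowSums(Mod(A)^2))
  cn <- sqrt(colSums(Mod(psi)^2))
  if (any(rn == 0)) abort("zero row in the sensing operator")
  if (any(cn == 0)) abort("zero column in the sparsity basis")
  G <- (A / rn) %*% (psi / rep(cn, each = n))
  sqrt(n) * max(Mod(G))
}

#' Randomized restricted-isometry surrogate
#'
#' Exact verification of the restricted isometry property is intractable, so
#' the constant is probed: `trials` random K-column submatrices of the
#' column-normalised operator are sampled and the worst deviation of their
#' squared extreme singular values from 1 is recorded,
#' `delta_hat = max(sigma_max^2 - 1, 1 - sigma_min^2)`. The draw passes when
#' `delta_hat < 0.5`.
#'
#' @param phi a `sensing_matrix` or matrix.
#' @param k sparsity level probed (>= 1).
#' @param trials number of random submatrices.
#' @param seed integer seed.
#' @return list with `delta_hat`, `pass`, and `reason` when failing by
#'   construction (`k > m` makes every submatrix rank deficient).
#' @export
rip_surrogate <- function(phi, k, trials = 100, seed = 1) {
  A <- as_operator(phi)
  if (k < 1 || trials < 1) abort("k and trials must be >= 1")
  if (k > ncol(A)) abort("k exceeds the number of columns")
  if (k > nrow(A))
    return(list(delta_hat = 1, pass = FALSE,
                reason = "submatrix rank-deficient by construction (k > m)"))
  cn <- sqrt(colSums(A^2))
  if (any(cn == 0)) abort("zero column in the sensing operator")
  A <- A / rep(cn, each = nrow(A))
  withr::with_seed(seed, {
    delta <- 0
    for (t in seq_len(trials)) {
      S <- sample.int(ncol(A), k)
      sv <- svd(A[, S, drop = FALSE], nu = 0, nv = 0)$d
      delta <- max(delta, sv[1]^2 - 1, 1 - sv[length(sv)]^2)
    }
    list(delta_hat = delta, pass = delta < 0.5, reason = NULL)
  })
}

#' Measurement-count bound
#'
#' Checks the compressed-sensing sufficient-measurement rule
#' `M >= beta * K * log(N / M)` (natural logarithm; `beta` defaults to 2).
#'
#' @param m,n,k measurement count, signal length and sparsity.
#' @param beta positive constant.
#' @return list with `beta`, `bound` (the right-hand side) and `satisfied`.
#' @export
measurement_bound <- function(m, n, k, beta = 2) {
  if (beta <= 0) abort("beta must be positive")
  bound <- beta * k * log(n / m)
  list(beta = beta, bound = bound, satisfied = m >= bound)
}

#' Draw a sensing matrix that passes the restricted-isometry surrogate
#'
#' Wraps [make_matrix()] + [rip_surrogate()]: a draw failing the surrogate at
#' sparsity `k` is regenerated with a fresh derived seed, up to `max_redraws`
#' times, after which an error reports the last `delta_hat`.
#'
#' @inheritParams make_matrix
#' @param k sparsity level the surrogate probes.
#' @param trials submatrices probed per draw.
#' @param max_redraws redraw budget.
#' @return a `sensing_matrix` whose surrogate check passed.
#' @export
make_verified_matrix <- function(family, m, n, k, seed = 1, trials = 50,
                                 max_redraws = 5) {
  for (attempt in 0:max_redraws) {
    s <- derive_seed(seed, attempt)
    phi <- make_matrix(family, m, n, seed = s)
    chk <- rip_surrogate(phi, k, trials = trials, seed = s)
    if (chk$pass) {
      phi$rip_delta_hat <- chk$delta_hat
      return(phi)
    }
  }
  abort("no %s draw passed the RIP surrogate after %d redraws (last delta_hat = %.3f)",
        family, max_redraws, chk$delta_hat)
}

new_compressed_segment <- function(measurements, matrix_id, source_n, seed = NA) {
  structure(list(measurements = as.numeric(measurements),
                 matrix_id = matrix_id, source_n = source_n, seed = seed),
            class = "compressed_segment")
}

#' @export
print.compressed_segment <- function(x, ...) {
  cat(sprintf("<compressed_segment> M=%d from N=%d (%s)\n",
              length(x$measurements), x$source_n, x$matrix_id))
  invisible(x)
}

#' Simulate the analog random-demodulator front end
#'
#' The sample stream is multiplied by an i.i.d. +/-1 chipping sequence at the
#' input rate (the Gilbert-multiplier stage) and then integrated-and-dumped
#' over consecutive windows of length `N/M` (the active-integrator stage).
#' When `M` does not divide `N` the tail is zero-padded and the original
#' length recorded. The equivalent structured sensing matrix (one chip block
#' per measurement row) is returned and satisfies
#' `measurements == matrix %*% samples` exactly.
#'
#' @param segment a [semg_segment()].
#' @param m number of measurements (`<= N`).
#' @param seed integer seed for the chip draw.
#' @param chips optional explicit +/-1 chip sequence (length >= padded N);
#'   overrides the seeded draw.
#' @return list with `compressed` (a `compressed_segment`) and `matrix`
#'   (an `rd_structured` `sensing_matrix`).
#' @export
simulate_random_demodulator <- function(segment, m, seed = 1, chips = NULL) {
  x <- segment$samples
  n0 <- length(x)
  if (m > n0) abort("m must not exceed the segment length")
  w <- ceiling(n0 / m)
  n_pad <- w * m
  if (is.null(chips)) {
    chips <- withr::with_seed(seed, sample(c(-1, 1), n_pad, replace = TRUE))
  } else {
    if (length(chips) < n_pad) abort("chips must have length >= %d", n_pad)
    chips <- chips[seq_len(n_pad)]
    if (!all(chips %in% c(-1, 1))) abort("chips must be +/-1")
  }
  xp <- c(x, numeric(n_pad - n0))
  meas <- as.numeric(rowsum(chips * xp, rep(seq_len(m), each = w)))
  ent <- matrix(0, m, n0)
  for (i in seq_len(m)) {
    idx <- ((i - 1) * w + 1):min(i * w, n0)
    if (idx[1] <= n0) ent[i, idx] <- chips[idx]
  }
  phi <- new_sensing_matrix(ent, "rd_structured", seed, column_normalized = FALSE)
  phi$chips <- chips
  phi$window <- w
  phi$source_n <- n0
  list(compressed = new_compressed_segment(meas, "rd_structured", n0, seed),
       matrix = phi)
}

#' Compress a segment (Algorithm I)
#'
#' Full transmitter-side flow: optionally verify the sensing matrix with the
#' restricted-isometry surrogate, dynamically threshold the segment, raise
#' the threshold fraction in steps of 0.01 until the sparsity level reaches
#' `sp_target` (erroring if the cap is hit first), check the
#' measurement-count bound, and form the measurement vector `C = Phi %*% D`.
#'
#' Pass `config = NULL` to skip thresholding for inputs that are already
#' exactly sparse (e.g. [generate_ksparse()] outputs).
#'
#' @param segment a [semg_segment()].
#' @param phi a `sensing_matrix` (or plain matrix) with `n` columns.
#' @param config a [threshold_config()], or `NULL` for raw compression.
#' @param sp_target sparsity level to reach before measuring (default 0.98).
#' @param fraction_cap largest threshold fraction tried (default 0.40).
#' @param beta constant of the measurement bound.
#' @param check_rip verify the matrix with [rip_surrogate()] at the achieved
#'   K; a failure downgrades to a recorded warning, not an error.
#' @return list with `compressed` (a `compressed_segment`), `report`
#'   (a `sparsity_report`), `fraction_used`, `bound` (see
#'   [measurement_bound()]) and `warnings` (character).
#' @export
compress <- function(segment, phi, config = threshold_config(),
                     sp_target = 0.98, fraction_cap = 0.40, beta = 2,
                     check_rip = FALSE) {
  A <- as_operator(phi)
  x <- segment$samples
  n <- length(x)
  if (ncol(A) != n) abort("matrix has %d columns but segment has %d samples", ncol(A), n)
  warnings <- character(0)
  if (is.null(config)) {
    d <- x
    k <- sum(d != 0)
    report <- sparsity_report(k, n)
    fraction <- NA_real_
  } else {
    fraction <- config$threshold_fraction
    res <- dynamic_threshold(segment, config)
    while (res$report$SP < sp_target && fraction < fraction_cap) {
      fraction <- min(fraction + 0.01, fraction_cap)
      res <- dynamic_threshold(segment, threshold_config(config$window_w, fraction))
    }
    if (res$report$SP < sp_target)
      abort("sparsity target %.3f unreachable at fraction cap %.2f (achieved SP = %.4f)",
            sp_target, fraction_cap, res$report$SP)
    d <- res$segment$samples
    k <- res$report$K
    report <- res$report
  }
  bound <- measurement_bound(nrow(A), n, max(k, 1), beta)
  if (!bound$satisfied)
    warnings <- c(warnings, sprintf("measurement bound violated: M=%d < %.1f", nrow(A), bound$bound))
  if (check_rip) {
    rip <- rip_surrogate(phi, max(k, 1), trials = 25,
                         seed = if (inherits(phi, "sensing_matrix")) phi$seed else 1)
    if (!rip$pass)
      warnings <- c(warnings, sprintf("RIP surrogate failed (delta_hat = %.3f)", rip$delta_hat))
  }
  meas <- drop(A %*% d)
  mat_id <- if (inherits(phi, "sensing_matrix")) phi$family else "matrix"
  sd_seed <- if (inherits(phi, "sensing_matrix")) phi$seed else NA
  list(compressed = new_compressed_segment(meas, mat_id, n, sd_seed),
       report = report, fraction_used = fraction, bound = bound,
       thresholded = d, warnings = warnings)
}

## ---- matrix persistence ---------------------------------------------------

#' Save / load a sensing matrix
#'
#' The dense entries go to a whitespace-delimited text file; family, seed and
#' dimensions go to a JSON sidecar (`<path>.json`).
#'
#' @param phi a `sensing_matrix`.
#' @param path file path for the entries.
#' @return `path` invisibly (`save_matrix`); a `sensing_matrix`
#'   (`load_matrix`).
#' @export
save_matrix <- function(phi, path) {
  stopifnot(inherits(phi, "sensing_matrix"))
  write.table(format(phi$entries, digits = 17, trim = TRUE, scientific = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(family = phi$family, seed = phi$seed,
                            m = phi$m, n = phi$n,
                            column_normalized = phi$column_normalized),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_matrix
#' @export
load_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ent <- as.matrix(read.table(path))
  dimnames(ent) <- NULL
  if (nrow(ent) != meta$m || ncol(ent) != meta$n)
    abort("matrix file %s does not match its sidecar dimensions", path)
  new_sensing_matrix(ent, meta$family, meta$seed, meta$column_normalized)
}
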