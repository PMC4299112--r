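# Sensing-dictionary selection (Algorithm II): sparse coding by orthogonal
# matching pursuit, K-SVD style atom updates, row selection, and nomination
# of the learned candidate versus a binary-Toeplitz reference by mutual
# coherence.

#' Orthogonal matching pursuit
#'
#' Greedy sparse coding: each iteration selects the atom most correlated
#' with the current residual (ties broken toward the lowest index), refits
#' all active coefficients by least squares, and stops after `k_max` atoms
#' or when the residual l2 norm drops to `tol`.
#'
#' @param dictionary N x A matrix with (near) unit-norm columns.
#' @param signal numeric vector of length N; must be finite.
#' @param k_max maximum number of atoms (>= 1).
#' @param tol absolute residual norm at which to stop.
#' @return a length-A coefficient vector with at most `k_max` nonzeros.
#' @export
omp <- function(dictionary, signal, k_max, tol = 1e-6) {
  check_finite(signal, "signal")
  if (k_max < 1) abort("k_max must be >= 1")
  A <- ncol(dictionary)
  coef <- numeric(A)
  res <- signal
  active <- integer(0)
  while (length(active) < k_max && l2norm(res) > tol) {
    corr <- abs(drop(crossprod(dictionary, res)))
    corr[active] <- -Inf
    j <- which.max(corr)  # which.max takes the lowest index on ties
    active <- c(active, j)
    fit <- qr.solve(dictionary[, active, drop = FALSE], signal)
    res <- signal - drop(dictionary[, active, drop = FALSE] %*% fit)
  }
  if (length(active)) coef[active] <- fit
  coef
}

# Fix atom sign so its largest-magnitude entry is positive.
fix_sign <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) s <- 1
  v * s
}

#' K-SVD style dictionary update
#'
#' For every atom used by at least one training signal, the restricted
#' residual matrix (signals minus the contribution of all *other* atoms,
#' columns limited to the users of this atom) is formed and replaced by its
#' best rank-1 approximation: the atom becomes the leading left singular
#' vector (sign-fixed) and the users' coefficients become `sigma_1` times the
#' leading right singular vector. Atoms used by no signal are re-drawn from
#' the currently worst-represented training signal. The total squared
#' representation error never increases.
#'
#' @param dictionary N x A matrix, unit-norm columns.
#' @param training_set N x P matrix of training signals.
#' @param codes A x P coefficient matrix (e.g. stacked [omp()] outputs).
#' @return list with updated `dictionary`, `codes`, and the resulting total
#'   squared `error`.
#' @export
svd_update <- function(dictionary, training_set, codes) {
  Y <- as.matrix(training_set)
  if (ncol(Y) == 0) abort("empty training set")
  D <- dictionary
  X <- codes
  for (j in seq_len(ncol(D))) {
    users <- which(X[j, ] != 0)
    if (length(users) == 0) {
      resid <- Y - D %*% X
      worst <- which.max(colSums(resid^2))
      cand <- Y[, worst]
      if (l2norm(cand) > 0) D[, j] <- fix_sign(cand / l2norm(cand))
      next
    }
    E <- Y[, users, drop = FALSE] - D %*% X[, users, drop = FALSE] +
      D[, j, drop = FALSE] %*% X[j, users, drop = FALSE]
    sv <- svd(E, nu = 1, nv = 1)
    u <- fix_sign(sv$u[, 1])
    flip <- sum(u * sv$u[, 1])  # +/- 1 from the sign fix
    D[, j] <- u
    X[j, users] <- sv$d[1] * sv$v[, 1] * flip
  }
  list(dictionary = D, codes = X, error = sum((Y - D %*% X)^2))
}

#' Row selection
#'
#' @param square_matrix an N x N matrix.
#' @param m number of rows to keep (`<= N`).
#' @param strategy `"uniform_random"` (without replacement) or `"leverage"`
#'   (rows ranked by squared norm of the corresponding rows of the left
#'   singular matrix, computed over singular values above numerical
#'   tolerance; ties broken toward the lowest index).
#' @param seed integer seed for the random strategy.
#' @return a sorted ("uniform_random") or rank-ordered ("leverage") integer
#'   index vector of length `m`.
#' @export
row_select <- function(square_matrix, m, strategy = c("uniform_random", "leverage"),
                       seed = 1) {
  strategy <- match.arg(strategy)
  n <- nrow(square_matrix)
  if (m > n) abort("m must not exceed the number of rows")
  if (m == n) return(seq_len(n))
  if (strategy == "uniform_random") {
    sort(withr::with_seed(seed, sample.int(n, m)))
  } else {
    sv <- svd(square_matrix)
    keep <- sv$d > max(sv$d) * 1e-10
    scores <- rowSums(sv$u[, keep, drop = FALSE]^2)
    order(-scores, seq_len(n))[seq_len(m)]
  }
}

#' Select the sensing dictionary (Algorithm II)
#'
#' End-to-end dictionary selection: training segments are dynamically
#' thresholded; a square dictionary is initialised from the training columns
#' (when at least N signals are available) or from a seeded noisy DCT basis;
#' OMP sparse coding and K-SVD atom updates alternate for `sweeps`
#' iterations (a signal's previous code is kept whenever greedy re-coding
#' would increase its residual, which makes the error history provably
#' non-increasing); `m` rows of the learned square matrix are then selected
#' and the candidate's mutual coherence against the sparsity basis is
#' compared with a freshly drawn binary-Toeplitz matrix of the same size and
#' seed. The lower-coherence candidate is nominated; ties go to the
#' binary-Toeplitz reference as the simpler operator.
#'
#' @param training_set list of [semg_segment()]s (equal length) or an N x P
#'   numeric matrix of training signals.
#' @param m number of measurement rows.
#' @param sweeps OMP/K-SVD alternations (default 10).
#' @param k_max OMP sparsity cap (default `ceiling(0.05 * N)`).
#' @param tol OMP residual tolerance.
#' @param seed integer seed governing initialisation, row selection and the
#'   reference draw.
#' @param config [threshold_config()] applied to the training segments, or
#'   `NULL` to train on the raw signals.
#' @param psi N x N sparsity basis for the coherence comparison (default:
#'   identity, i.e. time-domain sparsity).
#' @param row_strategy passed to [row_select()].
#' @return an object of class `sparse_dictionary`: `atoms` (N x N),
#'   `selected_rows`, `history` (per-sweep squared representation error),
#'   `verdict` (`"learned"` or `"bt_reference"`), both coherences, and `phi`
#'   (the nominated M x N `sensing_matrix`).
#' @export
select_sensing_dictionary <- function(training_set, m, sweeps = 10,
                                      k_max = NULL, tol = 1e-6, seed = 1,
                                      config = threshold_config(),
                                      psi = NULL,
                                      row_strategy = "uniform_random") {
  if (is.list(training_set) && !is.matrix(training_set)) {
    lens <- vapply(training_set, function(s) length(s$samples), integer(1))
    if (length(unique(lens)) != 1) abort("training signals have mixed lengths")
    if (!is.null(config))
      training_set <- lapply(training_set, function(s) dynamic_threshold(s, config)$segment)
    Y <- vapply(training_set, function(s) s$samples, numeric(lens[1]))
  } else {
    Y <- as.matrix(training_set)
  }
  n <- nrow(Y); p <- ncol(Y)
  if (p < 1) abort("at least one training segment is required")
  if (is.null(k_max)) k_max <- ceiling(0.05 * n)
  if (is.null(psi)) psi <- diag(n)

  D <- if (p >= n) {
    cols <- Y[, seq_len(n), drop = FALSE]
    apply(cols, 2, function(v) if (l2norm(v) > 0) v / l2norm(v) else {
      e <- numeric(n); e[1] <- 1; e
    })
  } else {
    withr::with_seed(derive_seed(seed, 1), {
      B <- dct_basis(n) + matrix(rnorm(n * n, sd = 0.01), n, n)
      apply(B, 2, function(v) v / l2norm(v))
    })
  }

  X <- matrix(0, n, p)
  history <- numeric(0)
  prev_res <- rep(Inf, p)
  for (sw in seq_len(sweeps)) {
    for (i in seq_len(p)) {
      cand <- omp(D, Y[, i], k_max = k_max, tol = tol)
      r_new <- sum((Y[, i] - D %*% cand)^2)
      if (r_new <= prev_res[i] + 1e-12) {
        X[, i] <- cand
        prev_res[i] <- r_new
      }
    }
    upd <- svd_update(D, Y, X)
    D <- upd$dictionary
    X <- upd$codes
    prev_res <- colSums((Y - D %*% X)^2)
    history <- c(history, upd$error)
  }

  rows <- row_select(D, m, strategy = row_strategy, seed = derive_seed(seed, 2))
  learned_phi <- D[rows, , drop = FALSE]
  bt <- make_matrix("binary_toeplitz", m, n, seed = derive_seed(seed, 3))
  # a candidate with an all-zero measurement row is degenerate; it can
  # never be nominated, so its coherence is taken as +Inf
  mu_learned <- tryCatch(coherence(learned_phi, psi), error = function(e) Inf)
  mu_bt <- coherence(bt, psi)
  verdict <- if (mu_learned < mu_bt) "learned" else "bt_reference"
  phi <- if (verdict == "learned") {
    new_sensing_matrix(learned_phi, "learned", seed, column_normalized = FALSE,
                       selected_rows = rows, square = D)
  } else bt
  structure(list(atoms = D, selected_rows = rows, history = history,
                 verdict = verdict, coherence_learned = mu_learned,
                 coherence_bt = mu_bt, phi = phi, seed = seed),
            class = "sparse_dictionary")
}

#' @export
print.sparse_dictionary <- function(x, ...) {
  cat(sprintf(paste0("<sparse_dictionary> %d atoms, verdict=%s ",
                     "(mu_learned=%.3f, mu_bt=%.3f)\n"),
              ncol(x$atoms), x$verdict, x$coherence_learned, x$coherence_bt))
  invisible(x)
}
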