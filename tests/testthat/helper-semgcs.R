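# Shared fixtures and independent oracles used across the suite.

# Exhaustive best-K least-squares fit: tries every size-k support and keeps
# the one with the smallest residual. Independent of OMP and of the ADMM
# solvers; only usable at toy sizes.
best_k_fit <- function(dictionary, signal, k) {
  n_atoms <- ncol(dictionary)
  best <- list(err = Inf, coef = numeric(n_atoms))
  for (S in utils::combn(n_atoms, k, simplify = FALSE)) {
    A <- dictionary[, S, drop = FALSE]
    fit <- tryCatch(qr.solve(A, signal), error = function(e) NULL)
    if (is.null(fit)) next
    err <- sum((signal - A %*% fit)^2)
    if (err < best$err) {
      coef <- numeric(n_atoms)
      coef[S] <- fit
      best <- list(err = err, coef = coef)
    }
  }
  best
}

# Plain random segment (dense noise) for property tests.
random_segment <- function(n, seed, fs = 2000) {
  withr::with_seed(seed, semgcs::semg_segment(rnorm(n), fs = fs))
}

rel_err <- function(x, x_hat) sqrt(sum((x - x_hat)^2)) / sqrt(sum(x^2))

expect_nonincreasing <- function(x, tol = 1e-9) {
  expect_true(all(diff(x) <= tol))
}
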