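# l1 basis pursuit, combined l1-l1 optimization, BSBL-EM and the router.

test_that("l1 solver handles identity measurement, zero data and tiny brute-forceable cases", {
  C <- c(0, 2, 0, -1.5, 0, 0)
  r_id <- solve_l1(C, diag(6), solver_config(epsilon = 0))
  expect_equal(r_id$d_hat, C, tolerance = 1e-8)

  phi <- make_matrix("bernoulli", 4, 6, seed = 2)
  r0 <- solve_l1(numeric(4), phi)
  expect_equal(r0$d_hat, numeric(6))
  expect_true(r0$converged)

  # 1-sparse, N=6, M=4: compare with exhaustive search over all supports
  # (gaussian draws: generic position, so the l1 optimum is the unique
  # sparsest feasible vector and the oracle comparison is well posed)
  for (seed in 1:10) {
    truth <- numeric(6)
    truth[withr::with_seed(seed, sample.int(6, 1))] <- 1.3
    A <- make_matrix("gaussian", 4, 6, seed = seed + 40)$entries
    A <- A / rep(sqrt(colSums(A^2)), each = 4)  # unit columns: 1-sparse BP is exact
    b <- drop(A %*% truth)
    rec <- solve_l1(b, A, solver_config(epsilon = 0))
    oracle <- best_k_fit(A, b, 1)
    expect_equal(rec$d_hat, oracle$coef, tolerance = 1e-6)
  }
})

test_that("converged l1 solutions are feasible within epsilon", {
  for (seed in 1:10) {
    seg <- generate_ksparse(64, 4, "time", seed = seed)
    phi <- make_matrix("bernoulli", 32, 64, seed = seed + 7)
    b <- drop(phi$entries %*% seg$samples)
    eps <- 1e-6
    rec <- solve_l1(b, phi, solver_config(epsilon = eps))
    expect_true(rec$converged)
    expect_lte(rec$residual, eps + 1e-6)
  }
})

test_that("l1-l1 with lambda 0 reduces to l1 and zero measurements give zero", {
  seg <- generate_ksparse(32, 2, "time", seed = 5)
  phi <- make_matrix("bernoulli", 16, 32, seed = 6)
  b <- drop(phi$entries %*% seg$samples)
  cfg0 <- solver_config(lambda = 0, epsilon = 1e-9, max_iter = 5000)
  r_l1l1 <- solve_l1l1(b, phi, cfg0)
  r_l1 <- solve_l1(b, phi, cfg0)
  expect_lt(max(abs(r_l1l1$d_hat - r_l1$d_hat)), 1e-6)

  expect_equal(solve_l1l1(numeric(16), phi)$d_hat, numeric(32))
})

test_that("the frequency penalty helps on frequency-sparse signals", {
  # paired comparison: single nonzero Fourier coefficient, M = N/4
  err_l1 <- err_l1l1 <- numeric(20)
  for (seed in 1:20) {
    seg <- generate_ksparse(64, 1, "frequency", seed = seed)
    phi <- make_matrix("bernoulli", 16, 64, seed = seed + 300)
    b <- drop(phi$entries %*% seg$samples)
    err_l1[seed] <- rel_err(seg$samples,
                            solve_l1(b, phi, solver_config(epsilon = 1e-8))$d_hat)
    err_l1l1[seed] <- rel_err(seg$samples,
                              solve_l1l1(b, phi, solver_config(lambda = 10, epsilon = 1e-8,
                                                               max_iter = 2000))$d_hat)
  }
  expect_lt(median(err_l1l1), median(err_l1))
  expect_lt(median(err_l1l1), 1e-4)
})

test_that("BSBL identifies a single active block and matches the support oracle", {
  seg <- generate_block_ar(128, 16, 1, r = 0.9, seed = 3)
  phi <- make_matrix("bernoulli", 64, 128, seed = 9)  # M = 4h
  b <- drop(phi$entries %*% seg$samples)
  rec <- solve_bsbl(b, phi, block_model(128, 16))
  expect_length(rec$active_blocks, 1)
  truth_block <- which(tapply(seg$samples, rep(1:8, each = 16),
                              function(v) any(v != 0)))
  expect_equal(rec$active_blocks, as.integer(truth_block))
  # oracle: least squares restricted to the true block
  idx <- (truth_block - 1) * 16 + 1:16
  ls <- qr.solve(phi$entries[, idx], b)
  oracle <- numeric(128); oracle[idx] <- ls
  expect_lt(max(abs(rec$d_hat - oracle)), 1e-4)

  z <- solve_bsbl(numeric(64), phi, block_model(128, 16))
  expect_equal(z$d_hat, numeric(128))
  expect_true(all(z$gamma == 0))
})

test_that("BSBL learns the intra-block AR coefficient", {
  r_hat <- vapply(1:20, function(seed) {
    seg <- generate_block_ar(128, 16, 3, r = 0.9, seed = seed)
    phi <- make_matrix("bernoulli", 64, 128, seed = seed + 100)  # M/N = 0.5
    solve_bsbl(drop(phi$entries %*% seg$samples), phi, block_model(128, 16))$r_hat
  }, numeric(1))
  expect_lt(abs(median(r_hat) - 0.9), 0.15)
})

test_that("BSBL with unit blocks recovers entry-wise sparse signals comparably to l1", {
  err_b <- err_l <- numeric(20)
  for (seed in 1:20) {
    seg <- generate_ksparse(64, 4, "time", seed = seed + 600)
    phi <- make_matrix("bernoulli", 32, 64, seed = seed + 700)
    b <- drop(phi$entries %*% seg$samples)
    err_b[seed] <- rel_err(seg$samples,
                           solve_bsbl(b, phi, block_model(64, 1))$d_hat)
    err_l[seed] <- rel_err(seg$samples,
                           solve_l1(b, phi, solver_config(epsilon = 1e-8))$d_hat)
  }
  expect_lt(median(err_b), 1e-3)
  expect_lt(median(err_l), 1e-5)
})

test_that("BSBL error does not grow with more measurements", {
  med_err <- vapply(c(32, 64, 96), function(m) {
    errs <- vapply(1:10, function(seed) {
      seg <- generate_block_ar(128, 16, 2, r = 0.8, seed = seed + 50)
      phi <- make_matrix("bernoulli", m, 128, seed = seed + 900)
      rel_err(seg$samples,
              solve_bsbl(drop(phi$entries %*% seg$samples), phi,
                         block_model(128, 16))$d_hat)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_nonincreasing(med_err, tol = 1e-8)
})

test_that("the router follows signal class and sparsity hints", {
  seg <- generate_ksparse(64, 3, "time", seed = 1)
  phi <- make_matrix("bernoulli", 32, 64, seed = 2)
  b <- drop(phi$entries %*% seg$samples)
  cfg <- solver_config(epsilon = 1e-8)

  expect_identical(reconstruct(b, phi, list(label = "healthy"), cfg)$route_taken, "l1")
  expect_identical(reconstruct(b, phi, list(label = "myopathy"), cfg)$route_taken, "l1")
  expect_identical(reconstruct(b, phi, list(label = "neuropathy", domain_hint = "unknown"),
                               cfg)$route_taken, "l1l1")
  expect_identical(reconstruct(b, phi, list(domain_hint = "block-sparse"),
                               cfg)$route_taken, "bsbl")
  expect_error(reconstruct(b, phi, list(domain_hint = "unknown"), cfg), "explicit route")

  # explicit override beats the class-based rule
  cfg_b <- solver_config(epsilon = 1e-8, route = "bsbl")
  expect_identical(reconstruct(b, phi, list(label = "healthy"), cfg_b,
                               model = block_model(64, 16))$route_taken, "bsbl")
})
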