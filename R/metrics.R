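# Compression-quality metrics (PRD, Monte-Carlo RMSE, SNR, accuracy,
# compression factor, sensitivity/specificity), a k-nearest-neighbour
# classification check, and the Monte-Carlo sweep harness.

#' Percentage root-mean-square difference
#'
#' `PRD = 100 * sqrt( sum((D - Dhat)^2) / sum(D^2) )`. The printed form of
#' the ratio (no square root, no percent scaling) is available via
#' `paper_literal = TRUE` for comparison.
#'
#' @param d original signal (nonzero).
#' @param d_hat reconstructed signal, same length.
#' @param paper_literal return the bare squared-error ratio instead.
#' @return PRD in percent (or the literal ratio).
#' @export
prd <- function(d, d_hat, paper_literal = FALSE) {
  if (length(d) != length(d_hat)) abort("length mismatch")
  den <- sum(d^2)
  if (den == 0) abort("PRD undefined for a zero reference signal")
  ratio <- sum((d - d_hat)^2) / den
  if (paper_literal) ratio else 100 * sqrt(ratio)
}

#' Monte-Carlo RMSE
#'
#' Mean over repetitions of the normalised error `||D_l - Dhat_l|| /
#' ||Dhat_l||` (the denominator is the norm of the *estimate*, as the metric
#' is defined).
#'
#' @param pairs list of length-2 lists/pairs `(d, d_hat)`.
#' @return the mean normalised l2 error over the `L = length(pairs)`
#'   repetitions.
#' @export
rmse_mc <- function(pairs) {
  if (length(pairs) < 1) abort("at least one Monte-Carlo pair is required")
  vals <- vapply(pairs, function(p) {
    dh <- p[[2]]
    nd <- l2norm(dh)
    if (nd == 0) abort("RMSE undefined for a zero estimate")
    l2norm(p[[1]] - dh) / nd
  }, numeric(1))
  mean(vals)
}

#' Reconstruction SNR in dB
#'
#' `SNR = 20 log10(||D|| / ||D - Dhat||)`, capped at 300 dB for exact
#' reconstructions.
#'
#' @inheritParams prd
#' @return SNR in dB.
#' @export
snr_db <- function(d, d_hat) {
  nd <- l2norm(d)
  if (nd == 0) abort("SNR undefined for a zero reference signal")
  err <- l2norm(d - d_hat)
  if (err == 0) return(300)
  min(20 * log10(nd / err), 300)
}

#' Reconstruction accuracy in percent
#'
#' `A = max(0, 100 * (1 - ||D - Dhat|| / ||D||))` — the complement of the
#' relative l2 error, floored at zero.
#'
#' @inheritParams prd
#' @return accuracy in percent.
#' @export
accuracy <- function(d, d_hat) {
  nd <- l2norm(d)
  if (nd == 0) abort("accuracy undefined for a zero reference signal")
  max(0, 100 * (1 - l2norm(d - d_hat) / nd))
}

#' Compression factor in percent
#'
#' `CF = (Db - Cb) / Db * 100` where `Db` and `Cb` are the bit budgets of
#' the original and compressed representations. With equal per-sample bit
#' depth this equals `(1 - M/N) * 100`.
#'
#' @param db_bits bits of the original signal (`> 0`).
#' @param cb_bits bits of the compressed signal (`0 <= Cb <= Db`).
#' @return CF in percent.
#' @export
cf <- function(db_bits, cb_bits) {
  if (db_bits <= 0 || cb_bits < 0 || cb_bits > db_bits)
    abort("require Db >= Cb >= 0 with Db > 0")
  (db_bits - cb_bits) / db_bits * 100
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp, tn, fp, fn)
  if (any(v < 0)) abort("counts must be nonnegative")
  if (sum(v) == 0) abort("at least one count must be positive")
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn), class = "confusion_counts")
}

#' Sensitivity and specificity
#'
#' Standard definitions `SEN = TP / (TP + FN)`, `SPE = TN / (TN + FP)`.
#' `paper_literal = TRUE` uses `SEN = TP / (TP + TN)` instead (the
#' denominator as printed in the source equation, retained for comparison).
#'
#' @param counts a [confusion_counts()].
#' @param paper_literal use the literal SEN denominator.
#' @return named numeric vector `c(sen = , spe = )`.
#' @export
sen_spe <- function(counts, paper_literal = FALSE) {
  sen_den <- if (paper_literal) counts$TP + counts$TN else counts$TP + counts$FN
  spe_den <- counts$TN + counts$FP
  if (sen_den == 0) abort("SEN undefined: empty positive class")
  if (spe_den == 0) abort("SPE undefined: empty negative class")
  c(sen = counts$TP / sen_den, spe = counts$TN / spe_den)
}

#' Per-segment classification features
#'
#' RMS amplitude, mean absolute value, zero-crossing count and mean
#' (spectral-centroid) frequency — the standard time/frequency sEMG feature
#' quartet.
#'
#' @param segment a [semg_segment()].
#' @return named numeric vector of length 4.
#' @export
segment_features <- function(segment) {
  x <- segment$samples
  n <- length(x)
  sp <- Mod(fft(x))^2
  half <- 2:floor(n / 2 + 1)
  freqs <- (half - 1) * segment$fs / n
  pw <- sp[half]
  mnf <- if (sum(pw) > 0) sum(freqs * pw) / sum(pw) else 0
  c(rms = sqrt(mean(x^2)),
    mav = mean(abs(x)),
    zc = sum(diff(sign(x[x != 0])) != 0),
    mnf = mnf)
}

#' K-nearest-neighbour classification of segments
#'
#' Features from [segment_features()] are standardised by the training mean
#' and standard deviation; prediction is a majority vote among the `k`
#' Euclidean nearest training segments, with ties broken toward the
#' alphabetically lowest class label.
#'
#' @param train_segments,test_segments lists of labelled [semg_segment()]s.
#' @param k neighbourhood size (default 5); every class must have at least
#'   `k` training segments.
#' @return list with `predictions`, `truth`, overall `accuracy_percent`, and
#'   `confusion` — a named list of one-vs-rest [confusion_counts()] per
#'   class.
#' @export
knn_classify <- function(train_segments, test_segments, k = 5) {
  tr_lab <- vapply(train_segments, function(s) s$label, character(1))
  te_lab <- vapply(test_segments, function(s) s$label, character(1))
  if (any(table(tr_lab) < k)) abort("every class needs at least k = %d training segments", k)
  Xtr <- t(vapply(train_segments, segment_features, numeric(4)))
  Xte <- t(vapply(test_segments, segment_features, numeric(4)))
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  classes <- sort(unique(tr_lab))
  pred <- vapply(seq_len(nrow(Xte)), function(i) {
    d2 <- rowSums(sweep(Xtr, 2, Xte[i, ])^2)
    nb <- tr_lab[order(d2, seq_along(d2))[seq_len(k)]]
    tab <- table(factor(nb, levels = classes))
    names(tab)[which.max(tab)]  # ties -> lowest label (levels are sorted)
  }, character(1))
  confusion <- lapply(classes, function(cl) {
    confusion_counts(tp = sum(pred == cl & te_lab == cl),
                     tn = sum(pred != cl & te_lab != cl),
                     fp = sum(pred == cl & te_lab != cl),
                     fn = sum(pred != cl & te_lab == cl))
  })
  names(confusion) <- classes
  list(predictions = pred, truth = te_lab,
       accuracy_percent = 100 * mean(pred == te_lab),
       confusion = confusion)
}

#' Monte-Carlo sweep harness
#'
#' Runs the generate / compress / reconstruct / score loop over a grid of
#' measurement counts and sparsity levels, averaging each cell over `L`
#' Monte-Carlo repetitions with fully derived (hence reproducible) seeds.
#'
#' @param sweep_spec a list with entries:
#'   \describe{
#'     \item{n}{segment length (default 1024).}
#'     \item{m_grid}{integer vector of measurement counts.}
#'     \item{k_grid}{integer vector of sparsity levels (nonzero counts).}
#'     \item{domain}{sparsity domain for the test vectors (default "time").}
#'     \item{family}{sensing-matrix family (default "bernoulli").}
#'     \item{route}{solver route (default "l1").}
#'     \item{L}{Monte-Carlo repetitions per cell (default 50).}
#'     \item{seed}{base seed (default 1).}
#'     \item{epsilon}{solver fidelity radius (default 1e-8).}
#'     \item{bits}{per-sample bit depth for the CF column (default 10).}
#'   }
#' @return a data frame with one row per grid cell: `n, m, k, ssr, cr, srd,
#'   sp, L, seed, rmse, prd_percent, snr_db, accuracy_percent, cf_percent`.
#'   `ssr = M/N`, `cr = N/M`, `srd = 1 - M/N` (the fraction of Nyquist-rate
#'   samples removed).
#' @export
run_sweep <- function(sweep_spec) {
  s <- sweep_spec
  n <- s$n %||% 1024
  m_grid <- s$m_grid
  k_grid <- s$k_grid
  if (is.null(m_grid) || is.null(k_grid) || length(m_grid) == 0 || length(k_grid) == 0)
    abort("sweep grid is empty: provide m_grid and k_grid")
  domain <- s$domain %||% "time"
  family <- s$family %||% "bernoulli"
  route <- s$route %||% "l1"
  L <- s$L %||% 50
  seed <- s$seed %||% 1
  epsilon <- s$epsilon %||% 1e-8
  bits <- s$bits %||% 10

  grid <- expand.grid(m = m_grid, k = k_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    m <- grid$m[cell]; k <- grid$k[cell]
    pairs <- vector("list", L)
    prds <- snrs <- accs <- numeric(L)
    for (l in seq_len(L)) {
      sd_l <- derive_seed(seed, cell * 1000 + l)
      seg <- generate_ksparse(n, k, domain = domain, seed = sd_l)
      phi <- make_matrix(family, m, n, seed = derive_seed(sd_l, 1))
      cmp <- compress(seg, phi, config = NULL)
      cfg <- solver_config(epsilon = epsilon, route = route)
      rec <- reconstruct(cmp$compressed, phi, metadata = seg, config = cfg)
      pairs[[l]] <- list(seg$samples, rec$d_hat)
      prds[l] <- prd(seg$samples, rec$d_hat)
      snrs[l] <- snr_db(seg$samples, rec$d_hat)
      accs[l] <- accuracy(seg$samples, rec$d_hat)
    }
    data.frame(n = n, m = m, k = k, ssr = m / n, cr = n / m, srd = 1 - m / n,
               sp = (n - k) / n, L = L, seed = seed,
               rmse = rmse_mc(pairs), prd_percent = mean(prds),
               snr_db = mean(snrs), accuracy_percent = mean(accs),
               cf_percent = cf(n * bits, m * bits))
  })
  do.call(rbind, rows)
}
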