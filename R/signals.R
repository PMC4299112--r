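# Signal segments: synthetic sEMG generation, exactly-sparse test vectors,
# dynamic thresholding for sparsity control, and CSV/WFDB record I/O.

SEGMENT_LABELS <- c("healthy", "myopathy", "neuropathy", "sparse-test")
DOMAIN_HINTS <- c("time-sparse", "frequency-sparse", "block-sparse", "unknown")

# Morphology constants for the synthetic MUAP-train model. The clinical
# directions matter, not the absolute values: neuropathic muscle recruits
# fewer, larger motor units with longer-duration potentials firing slowly;
# myopathic muscle recruits many small, short-duration units firing densely.
MUAP_CLASS_PARAMS <- list(
  healthy    = list(n_units = 18, rate_hz = 14, dur_ms = 8,  amp = 1.0),
  myopathy   = list(n_units = 30, rate_hz = 22, dur_ms = 4,  amp = 0.45),
  neuropathy = list(n_units = 5,  rate_hz = 8,  dur_ms = 15, amp = 1.8)
)

#' Construct a signal segment
#'
#' An N-sample real-valued sEMG window with sampling rate, class label and a
#' sparsity-domain hint used by the reconstruction router.
#'
#' @param samples numeric vector, length >= 2, all finite.
#' @param fs sampling rate in Hz (> 0).
#' @param label one of `"healthy"`, `"myopathy"`, `"neuropathy"`,
#'   `"sparse-test"`.
#' @param domain_hint one of `"time-sparse"`, `"frequency-sparse"`,
#'   `"block-sparse"`, `"unknown"`.
#' @param events optional data frame of generator events (MUAP onsets).
#' @return an object of class `semg_segment`.
#' @export
semg_segment <- function(samples, fs, label = "sparse-test",
                         domain_hint = "unknown", events = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) abort("a segment needs at least 2 samples")
  check_finite(samples, "segment samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("fs must be a positive number")
  if (!label %in% SEGMENT_LABELS)
    abort("unknown label '%s'; allowed labels: %s", label,
          paste(SEGMENT_LABELS, collapse = ", "))
  if (!domain_hint %in% DOMAIN_HINTS)
    abort("unknown domain_hint '%s'; allowed: %s", domain_hint,
          paste(DOMAIN_HINTS, collapse = ", "))
  structure(list(samples = samples, fs = fs, label = label,
                 domain_hint = domain_hint, events = events),
            class = "semg_segment")
}

#' @export
print.semg_segment <- function(x, ...) {
  cat(sprintf("<semg_segment> %d samples @ %g Hz, label=%s, hint=%s\n",
              length(x$samples), x$fs, x$label, x$domain_hint))
  invisible(x)
}

#' @export
length.semg_segment <- function(x) length(x$samples)

# Biphasic MUAP template: first derivative of a Gaussian, unit peak amplitude.
muap_template <- function(dur_samples) {
  tt <- seq(-1, 1, length.out = max(3L, dur_samples))
  w <- -tt * exp(-(tt^2) / (2 * 0.3^2))
  w / max(abs(w))
}

#' Generate a synthetic sEMG segment
#'
#' Builds a motor-unit action-potential (MUAP) train: per motor unit, a
#' biphasic template is convolved with a renewal firing train (gamma
#' inter-spike intervals, CV ~ 0.2), the unit trains are summed, additive
#' Gaussian measurement noise is applied, and the segment is normalised to
#' unit peak amplitude. Class morphology follows the stored constants:
#' neuropathy uses fewer, larger, longer MUAPs; myopathy uses denser, smaller,
#' shorter MUAPs. The MUAP onset log is kept in `$events` so firing density
#' can be audited.
#'
#' @param label `"healthy"`, `"myopathy"` or `"neuropathy"`.
#' @param n segment length in samples (>= 64).
#' @param fs sampling rate in Hz.
#' @param seed integer seed; fixes the whole generation stream.
#' @param noise_sd additive Gaussian noise level relative to signal RMS.
#' @return a [semg_segment()] with `max(abs(samples)) == 1`.
#' @export
generate_semg <- function(label, n = 1024, fs = 2000, seed = 1, noise_sd = 0.05) {
  if (!label %in% names(MUAP_CLASS_PARAMS))
    abort("unknown label '%s'; allowed labels: %s", label,
          paste(names(MUAP_CLASS_PARAMS), collapse = ", "))
  if (n < 64) abort("generate_semg requires n >= 64")
  p <- MUAP_CLASS_PARAMS[[label]]
  withr::with_seed(seed, {
    dur <- max(3L, round(p$dur_ms / 1000 * fs))
    tmpl <- muap_template(dur)
    x <- numeric(n + dur)
    ev_unit <- integer(0); ev_onset <- integer(0)
    for (u in seq_len(p$n_units)) {
      amp <- p$amp * runif(1, 0.6, 1.4)
      mean_isi <- fs / p$rate_hz
      # renewal train: gamma ISIs with shape 25 -> CV = 0.2
      t_cur <- runif(1, 0, mean_isi)
      while (t_cur < n) {
        onset <- as.integer(floor(t_cur)) + 1L
        idx <- onset:(onset + dur - 1L)
        x[idx] <- x[idx] + amp * tmpl[seq_along(idx)]
        ev_unit <- c(ev_unit, u); ev_onset <- c(ev_onset, onset)
        t_cur <- t_cur + rgamma(1, shape = 25, scale = mean_isi / 25)
      }
    }
    x <- x[seq_len(n)]
    x <- x + rnorm(n, sd = noise_sd * max(sd(x), 1e-12))
    x <- x / max(abs(x))
    hint <- if (label == "neuropathy") "frequency-sparse" else "time-sparse"
    semg_segment(x, fs = fs, label = label, domain_hint = hint,
                 events = data.frame(unit = ev_unit, onset = ev_onset))
  })
}

#' Generate an exactly K-sparse test vector
#'
#' Produces a unit-l2-norm segment with exactly `k` nonzero coefficients in
#' the stated domain. Nonzero magnitudes are drawn uniformly in \[0.3, 1\]
#' (bounded away from zero) with random signs before normalisation.
#'
#' For `domain = "block"` the nonzeros are confined to
#' `ceiling(k / block_size)` blocks of a non-overlapping partition into
#' blocks of `block_size` samples; all other blocks are exactly zero.
#'
#' @param n length (>= 2).
#' @param k number of nonzeros, `1 <= k <= n`.
#' @param domain `"time"`, `"frequency"` or `"block"`.
#' @param seed integer seed.
#' @param block_size block length for `domain = "block"` (must divide `n`).
#' @param fs nominal sampling rate attached to the segment.
#' @return a [semg_segment()] labelled `"sparse-test"`.
#' @export
generate_ksparse <- function(n, k, domain = c("time", "frequency", "block"),
                             seed = 1, block_size = 16, fs = 2000) {
  domain <- match.arg(domain)
  if (k < 1 || k > n) abort("k must satisfy 1 <= k <= n (got k=%d, n=%d)", k, n)
  withr::with_seed(seed, {
    vals <- runif(k, 0.3, 1) * sample(c(-1, 1), k, replace = TRUE)
    if (domain == "time") {
      x <- numeric(n)
      x[sample.int(n, k)] <- vals
      hint <- "time-sparse"
    } else if (domain == "frequency") {
      coef <- numeric(n)
      coef[sample.int(n, k)] <- vals
      x <- drop(crossprod(fourier_basis(n), coef))  # synthesis t(F) %*% coef
      hint <- "frequency-sparse"
    } else {
      if (n %% block_size != 0) abort("block_size must divide n")
      g <- n / block_size
      n_active <- ceiling(k / block_size)
      if (n_active > g) abort("k too large for the block partition")
      blocks <- sort(sample.int(g, n_active))
      pos <- unlist(lapply(seq_along(blocks), function(i) {
        take <- if (i < length(blocks)) block_size else k - (i - 1) * block_size
        (blocks[i] - 1) * block_size + seq_len(take)
      }))
      x <- numeric(n)
      x[pos] <- vals
      hint <- "block-sparse"
    }
    x <- x / l2norm(x)
    semg_segment(x, fs = fs, label = "sparse-test", domain_hint = hint)
  })
}

#' Generate a block-sparse segment with intra-block AR(1) correlation
#'
#' Support for block sparse Bayesian learning experiments: a few active
#' blocks, each drawn from a zero-mean Gaussian with Toeplitz AR(1)
#' covariance `r^|i-j|`, all remaining blocks exactly zero.
#'
#' @param n length; `block_size` must divide it.
#' @param block_size samples per block.
#' @param n_active number of active blocks.
#' @param r intra-block lag-1 correlation, `|r| < 1`.
#' @param seed integer seed.
#' @param fs nominal sampling rate.
#' @return a unit-norm [semg_segment()] with hint `"block-sparse"`.
#' @export
generate_block_ar <- function(n, block_size, n_active, r = 0.9, seed = 1,
                              fs = 2000) {
  if (n %% block_size != 0) abort("block_size must divide n")
  if (abs(r) >= 1) abort("|r| must be < 1")
  g <- n / block_size
  if (n_active > g) abort("n_active exceeds the number of blocks")
  Sig <- toeplitz(r^(0:(block_size - 1)))
  L <- chol(Sig)
  withr::with_seed(seed, {
    x <- numeric(n)
    for (b in sort(sample.int(g, n_active))) {
      idx <- (b - 1) * block_size + seq_len(block_size)
      x[idx] <- drop(crossprod(L, rnorm(block_size)))
    }
    x <- x / l2norm(x)
    semg_segment(x, fs = fs, label = "sparse-test", domain_hint = "block-sparse")
  })
}

#' Dynamic-thresholding configuration
#'
#' @param window_w sliding-average window length in samples for DC removal
#'   (default 8; the useful range is about 5-10).
#' @param threshold_fraction threshold as a fraction of the DC-removed
#'   signal's peak-to-peak amplitude, in \[0, 1\] (default 0.10).
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(window_w = 8, threshold_fraction = 0.10) {
  if (window_w < 1) abort("window_w must be >= 1")
  if (threshold_fraction < 0 || threshold_fraction > 1)
    abort("threshold_fraction must lie in [0, 1]")
  structure(list(window_w = as.integer(window_w),
                 threshold_fraction = threshold_fraction),
            class = "threshold_config")
}

sparsity_report <- function(k, n, threshold_value = NA_real_) {
  structure(list(K = as.integer(k), N = as.integer(n),
                 SP = (n - k) / n, threshold_value = threshold_value),
            class = "sparsity_report")
}

#' @export
print.sparsity_report <- function(x, ...) {
  cat(sprintf("<sparsity_report> K=%d of N=%d, SP=%.4f\n", x$K, x$N, x$SP))
  invisible(x)
}

# Centered sliding mean with edge truncation: window for index i covers
# max(1, i - floor((w-1)/2)) .. min(n, i + floor(w/2)).
sliding_mean <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - floor((w - 1) / 2))
  hi <- pmin(n, seq_len(n) + floor(w / 2))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Dynamic thresholding of a segment
#'
#' Sparsity control in two steps: (1) the slowly varying DC level is
#' estimated by a centered sliding average of `window_w` samples (edges
#' truncated) and subtracted; (2) entries of the DC-removed signal with
#' magnitude strictly below `threshold_fraction` times its peak-to-peak
#' amplitude are set exactly to zero. Raising the threshold fraction never
#' decreases the resulting sparsity level SP = (N - K)/N.
#'
#' @param segment a [semg_segment()].
#' @param config a [threshold_config()].
#' @return a list with elements `segment` (thresholded) and `report`
#'   (a `sparsity_report` with `K`, `SP` and the absolute threshold used).
#' @export
dynamic_threshold <- function(segment, config = threshold_config()) {
  stopifnot(inherits(segment, "semg_segment"), inherits(config, "threshold_config"))
  x <- segment$samples
  n <- length(x)
  if (n < config$window_w) abort("segment shorter than window_w (%d < %d)", n, config$window_w)
  y <- x - sliding_mean(x, config$window_w)
  tv <- config$threshold_fraction * (max(y) - min(y))
  y[abs(y) < tv] <- 0
  k <- sum(y != 0)
  list(segment = semg_segment(y, fs = segment$fs, label = segment$label,
                              domain_hint = segment$domain_hint,
                              events = segment$events),
       report = sparsity_report(k, n, threshold_value = tv))
}

#' Normalise a segment to unit peak amplitude
#'
#' @param segment a [semg_segment()].
#' @return the segment scaled so `max(abs(samples)) == 1` (zero segments are
#'   returned unchanged).
#' @export
normalize_segment <- function(segment) {
  m <- max(abs(segment$samples))
  if (m == 0) return(segment)
  semg_segment(segment$samples / m, fs = segment$fs, label = segment$label,
               domain_hint = segment$domain_hint, events = segment$events)
}

## ---- record I/O -----------------------------------------------------------

#' Write a segment to disk
#'
#' CSV is a one-column text format with a comment header carrying `fs`,
#' `label` and `domain_hint`; samples are printed with 17 significant digits
#' so the read/write round trip is exact. WFDB writes a minimal header
#' (`.hea`) plus a format-16 (little-endian int16) signal file (`.dat`) with
#' a stored gain; the round trip is exact to 1/gain.
#'
#' @param segment a [semg_segment()].
#' @param path output path. For WFDB, the record name: `path.hea` and
#'   `path.dat` are written.
#' @param format `"csv"` or `"wfdb"`.
#' @param gain WFDB integer gain (ADC units per signal unit).
#' @return `path`, invisibly.
#' @export
write_segment <- function(segment, path, format = c("csv", "wfdb"), gain = 8192) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# fs: %.17g", segment$fs),
                 sprintf("# label: %s", segment$label),
                 sprintf("# domain_hint: %s", segment$domain_hint),
                 sprintf("%.17g", segment$samples)), con)
  } else {
    rec <- basename(path)
    n <- length(segment$samples)
    writeLines(c(sprintf("%s 1 %.17g %d", rec, segment$fs, n),
                 sprintf("%s.dat 16 %d 16 0 0 0 0 %s", rec, gain, segment$label)),
               paste0(path, ".hea"))
    adc <- as.integer(round(segment$samples * gain))
    if (any(abs(adc) > 32767)) abort("gain too large: ADC values overflow int16")
    writeBin(adc, paste0(path, ".dat"), size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a segment from disk
#'
#' @param path input path (for WFDB, the record name without extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param channel WFDB channel to extract for multi-channel records
#'   (default 0, i.e. the first signal; the choice is reported via `message`).
#' @return a [semg_segment()].
#' @export
read_segment <- function(path, format = c("csv", "wfdb"), channel = 0) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    get_field <- function(key, default) {
      m <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
      if (length(m) == 0) return(default)
      trimws(sub(sprintf("^#\\s*%s:", key), "", m[1]))
    }
    fs <- as.numeric(get_field("fs", NA))
    if (is.na(fs)) abort("CSV header missing fs: %s", path)
    label <- get_field("label", "sparse-test")
    hint <- get_field("domain_hint", "unknown")
    body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    vals <- suppressWarnings(as.numeric(body))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      abort("non-numeric sample at data row %d of %s: '%s'", bad, path, body[bad])
    }
    semg_segment(vals, fs = fs, label = label, domain_hint = hint)
  } else {
    hea <- readLines(paste0(path, ".hea"))
    top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
    if (length(top) < 4) abort("malformed WFDB header (line 1): %s.hea", path)
    nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
    if (channel < 0 || channel >= nsig) abort("channel %d out of range (record has %d signals)", channel, nsig)
    if (nsig > 1) message(sprintf("WFDB record has %d channels; reading channel %d", nsig, channel))
    sig <- strsplit(trimws(hea[2 + channel]), "\\s+")[[1]]
    if (length(sig) < 3) abort("malformed WFDB signal line %d in %s.hea", 2 + channel, path)
    if (sig[2] != "16") abort("unsupported WFDB format '%s' (only format 16)", sig[2])
    gain <- as.numeric(sig[3])
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default gain
    dat <- strsplit(trimws(hea[2]), "\\s+")[[1]][1]
    raw <- readBin(file.path(dirname(path), dat), what = "integer", size = 2,
                   n = nsamp * nsig, endian = "little")
    label <- if (length(sig) >= 9 && sig[9] %in% SEGMENT_LABELS) sig[9] else "sparse-test"
    semg_segment(raw[seq(channel + 1, length(raw), by = nsig)] / gain,
                 fs = fs, label = label)
  }
}
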