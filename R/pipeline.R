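# End-to-end pipeline: generate -> threshold -> compress -> reconstruct ->
# score, with artifacts and a seed/decision log written to disk.

#' Validate a pipeline configuration
#'
#' One document holding every stage's settings. Validation checks mutual
#' consistency (M <= N, block size divides N, known labels/routes/families)
#' before any computation runs.
#'
#' @param label signal class: `"healthy"`, `"myopathy"`, `"neuropathy"` or
#'   `"sparse-test"` (an exactly K-sparse test vector).
#' @param n,fs segment length and sampling rate.
#' @param k nonzero count for `label = "sparse-test"`.
#' @param domain sparsity domain for the test vector.
#' @param m measurement count.
#' @param family sensing-matrix family.
#' @param route solver route (`"auto"` routes by class).
#' @param threshold a [threshold_config()], or `NULL` to skip thresholding
#'   (the default for exactly sparse inputs).
#' @param block_size BSBL block size (must divide `n`).
#' @param epsilon solver fidelity radius.
#' @param seed base seed for every random draw in the run.
#' @param bits per-sample bit depth used by the compression-factor column.
#' @param out_dir artifact directory (`NULL` for a temporary directory).
#' @return a validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(label = "sparse-test", n = 1024, fs = 2000, k = 11,
                            domain = "time", m = 250, family = "bernoulli",
                            route = "auto", threshold = NULL, block_size = 16,
                            epsilon = 1e-8, seed = 1, bits = 10,
                            out_dir = NULL) {
  if (!label %in% SEGMENT_LABELS)
    abort("unknown label '%s'; allowed: %s", label, paste(SEGMENT_LABELS, collapse = ", "))
  if (m > n) abort("invalid config: m = %d exceeds n = %d", m, n)
  if (m < 1 || n < 64) abort("invalid config: need m >= 1 and n >= 64")
  if (n %% block_size != 0) abort("invalid config: block_size %d does not divide n = %d", block_size, n)
  if (!family %in% c("bernoulli", "gaussian", "binary_toeplitz"))
    abort("unknown matrix family '%s'", family)
  if (!route %in% c("auto", "l1", "l1l1", "bsbl")) abort("unknown route '%s'", route)
  if (!is.null(threshold)) stopifnot(inherits(threshold, "threshold_config"))
  structure(list(label = label, n = n, fs = fs, k = k, domain = domain, m = m,
                 family = family, route = route, threshold = threshold,
                 block_size = block_size, epsilon = epsilon, seed = seed,
                 bits = bits, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Generates (or loads) a segment, applies dynamic thresholding when
#' configured, compresses with the configured sensing matrix, reconstructs
#' through the routed solver, scores the result, and writes the segment,
#' measurements, reconstruction, a one-row metrics CSV and a JSON run log
#' (seeds, route, threshold fraction, warnings) to `out_dir`. Identical
#' configurations produce byte-identical metrics files.
#'
#' @param config a [pipeline_config()].
#' @param segment optional pre-built [semg_segment()]; skips generation.
#' @return invisibly, a list with `segment`, `compressed`, `result`,
#'   `metrics` (data frame) and `paths`.
#' @export
run_pipeline <- function(config, segment = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir %||% tempfile("semgcs_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(segment)) {
    segment <- if (config$label == "sparse-test") {
      generate_ksparse(config$n, config$k, domain = config$domain,
                       seed = config$seed, block_size = config$block_size,
                       fs = config$fs)
    } else {
      generate_semg(config$label, n = config$n, fs = config$fs, seed = config$seed)
    }
  }
  phi <- make_matrix(config$family, config$m, config$n,
                     seed = derive_seed(config$seed, 11))
  cmp <- compress(segment, phi, config = config$threshold)
  scfg <- solver_config(epsilon = config$epsilon, route = config$route)
  rec <- reconstruct(cmp$compressed, phi, metadata = segment, config = scfg,
                     model = block_model(config$n, config$block_size))

  reference <- cmp$thresholded  # score against what was actually measured
  metrics <- data.frame(
    label = segment$label, route = rec$route_taken,
    n = config$n, m = config$m, k = cmp$report$K,
    sp = cmp$report$SP, ssr = config$m / config$n, cr = config$n / config$m,
    prd_percent = prd(reference, rec$d_hat),
    rmse = l2norm(reference - rec$d_hat) / max(l2norm(rec$d_hat), 1e-300),
    snr_db = snr_db(reference, rec$d_hat),
    accuracy_percent = accuracy(reference, rec$d_hat),
    cf_percent = cf(config$n * config$bits, config$m * config$bits))

  paths <- list(segment = file.path(out_dir, "segment.csv"),
                thresholded = file.path(out_dir, "thresholded.csv"),
                measurements = file.path(out_dir, "measurements.csv"),
                reconstruction = file.path(out_dir, "reconstruction.csv"),
                metrics = file.path(out_dir, "metrics.csv"),
                log = file.path(out_dir, "run_log.json"))
  write_segment(segment, paths$segment)
  write_segment(semg_segment(reference, segment$fs, segment$label,
                             segment$domain_hint), paths$thresholded)
  writeLines(sprintf("%.17g", cmp$compressed$measurements), paths$measurements)
  write_segment(semg_segment(rec$d_hat, segment$fs, segment$label,
                             segment$domain_hint), paths$reconstruction)
  write.csv(format(metrics, digits = 15), paths$metrics, row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, matrix_seed = derive_seed(config$seed, 11),
         family = config$family, route_taken = rec$route_taken,
         fraction_used = cmp$fraction_used,
         bound_satisfied = cmp$bound$satisfied,
         converged = rec$converged, iterations = rec$iterations,
         warnings = cmp$warnings),
    paths$log, auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(segment = segment, compressed = cmp, result = rec,
                 metrics = metrics, paths = paths))
}
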