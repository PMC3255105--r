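#' Pipeline configuration
#'
#' Bundles the tunable parameters of preprocessing, peak detection and
#' screening.  Defaults follow the published analysis settings: peaks
#' detected at signal-to-noise >= 3 with a 20% minimum peak threshold,
#' clusters completed within a 0.5% mass window at second-pass
#' signal-to-noise >= 2, the mass range restricted to 2,000-20,000 Da,
#' and two significance levels (0.05 for reporting, 1e-4 for the strict
#' screen).
#'
#' @param mz_min,mz_max Analysis mass window in Da.
#' @param snr_first_pass Signal-to-noise threshold for first-pass peak
#'   detection.
#' @param min_peak_threshold Minimum fraction of spectra a first-pass
#'   peak must appear in for its cluster to be retained.
#' @param cluster_window Total cluster mass window as a fraction of the
#'   cluster centre m/z (0.005 = 0.5%, i.e. +/- 0.25%).
#' @param snr_second_pass Relaxed signal-to-noise threshold used when
#'   completing the sample-by-cluster matrix.
#' @param baseline_half_width Half-width, in grid points, of the
#'   rolling-minimum/rolling-mean baseline estimator.
#' @param noise_window Window, in grid points, of the sliding-MAD noise
#'   estimator (must be >= 11).
#' @param cv_folds Folds for cross-validated tree evaluation.
#' @param alpha_report,alpha_strict Reporting and strict significance
#'   levels for the univariate screen.
#' @param seed Optional integer seed recorded with results.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mz_min = 2000, mz_max = 20000,
                            snr_first_pass = 3, min_peak_threshold = 0.20,
                            cluster_window = 0.005, snr_second_pass = 2,
                            baseline_half_width = 200L, noise_window = 151L,
                            cv_folds = 10L, alpha_report = 0.05,
                            alpha_strict = 1e-4, seed = NULL) {
  if (!(mz_min > 0 && mz_min < mz_max))
    stop("need 0 < mz_min < mz_max")
  if (snr_second_pass > snr_first_pass)
    stop("snr_second_pass must be <= snr_first_pass")
  if (!(min_peak_threshold > 0 && min_peak_threshold <= 1))
    stop("min_peak_threshold must be in (0, 1]")
  if (noise_window < 11) stop("noise_window must be >= 11 points")
  structure(list(mz_min = mz_min, mz_max = mz_max,
                 snr_first_pass = snr_first_pass,
                 min_peak_threshold = min_peak_threshold,
                 cluster_window = cluster_window,
                 snr_second_pass = snr_second_pass,
                 baseline_half_width = as.integer(baseline_half_width),
                 noise_window = as.integer(noise_window),
                 cv_folds = as.integer(cv_folds),
                 alpha_report = alpha_report, alpha_strict = alpha_strict,
                 seed = seed),
            class = "pipeline_config")
}

#' Read or write a pipeline/generator configuration as JSON
#'
#' Configurations are stored as plain JSON so they diff cleanly and need
#' no extra parser.  Fields absent from the file keep their defaults.
#'
#' @param path JSON file path.
#' @param config A `pipeline_config`.
#' @return `read_config()` returns a [pipeline_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
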