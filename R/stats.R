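#' Pooled-variance two-sample t statistic from summary statistics
#'
#' Classical Student t (pooled variance, `n1 + n2 - 2` degrees of
#' freedom) computed from per-group summaries, with a two-sided
#' p-value.  Degenerate zero-variance input yields `t = 0, p = 1` when
#' the means agree and a flagged `p = 0` separation when they differ.
#'
#' @param n1,mean1,sd1 Size, mean and SD of group 1.
#' @param n2,mean2,sd2 Size, mean and SD of group 2.
#' @param welch Use the Welch (unequal-variance) form instead.
#' @return A list with `t_stat`, `p_value`, `df` and `degenerate`
#'   (`TRUE` when the pooled variance is zero).
#' @export
t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2)
      return(list(t_stat = 0, p_value = 1, df = n1 + n2 - 2, degenerate = TRUE))
    return(list(t_stat = sign(mean1 - mean2) * Inf, p_value = 0,
                df = n1 + n2 - 2, degenerate = TRUE))
  }
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  list(t_stat = t, p_value = 2 * stats::pt(-abs(t), df), df = df,
       degenerate = FALSE)
}

#' Per-cluster Student t screen of a peak matrix
#'
#' Compares node-positive against node-negative intensities for every
#' peak cluster with the pooled-variance two-sample t-test (two-sided),
#' mirroring the published univariate screen.  A Bonferroni-adjusted
#' p-value column is included for transparency but is not used for
#' selection.
#'
#' @param pm A [peak_matrix()] containing both classes (>= 2 samples
#'   each).
#' @param alpha Significance level recorded in `significant_at_alpha`.
#' @param welch Use the Welch form.
#' @return `data.frame`, one row per cluster, sorted by ascending
#'   p-value: `mz_center`, per-class `mean`/`sd`, `t_stat` (absolute
#'   value, sign in `t_sign`), `p_value`, `p_bonferroni`,
#'   `significant_at_alpha`, `degenerate`.
#' @export
t_test_peaks <- function(pm, alpha = 0.05, welch = FALSE) {
  stopifnot(inherits(pm, "peak_matrix"))
  pos <- pm$labels == "node_positive"
  neg <- pm$labels == "node_negative"
  if (sum(pos) < 2 || sum(neg) < 2)
    stop("both classes need at least two samples")
  res <- lapply(seq_len(ncol(pm$values)), function(j) {
    x <- pm$values[pos, j]; y <- pm$values[neg, j]
    tt <- t_from_summary(length(x), mean(x), stats::sd(x),
                         length(y), mean(y), stats::sd(y), welch = welch)
    data.frame(mz_center = pm$clusters$mz_center[j],
               mean_pos = mean(x), sd_pos = stats::sd(x),
               mean_neg = mean(y), sd_neg = stats::sd(y),
               t_stat = abs(tt$t_stat), t_sign = sign(tt$t_stat),
               p_value = tt$p_value, degenerate = tt$degenerate)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(res$p_value * nrow(res), 1)
  res$significant_at_alpha <- res$p_value < alpha
  res[order(res$p_value, res$mz_center), , drop = FALSE]
}

#' Select differential clusters at two significance levels
#'
#' The published analysis states a strict threshold (P < 1e-4) while
#' its reported peak table uses P < 0.05; both screens are surfaced
#' rather than reconciled.  No multiple-testing correction is applied,
#' mirroring the original analysis.
#'
#' @param results Output of [t_test_peaks()].
#' @param alpha_strict Strict level (default 1e-4).
#' @param alpha_report Reporting level (default 0.05).
#' @return A list with `strict` and `reported`, each a vector of
#'   cluster m/z centres.
#' @export
screen_differential <- function(results, alpha_strict = 1e-4,
                                alpha_report = 0.05) {
  if (!nrow(results)) stop("empty results table")
  list(strict = results$mz_center[results$p_value < alpha_strict],
       reported = results$mz_center[results$p_value < alpha_report])
}

#' Pearson chi-square comparison of two rates
#'
#' Chi-square on the 2x2 success/failure table, 1 degree of freedom,
#' without continuity correction by default.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param correct Apply the Yates continuity correction.
#' @return A list with `chi2` and `p_value`.
#' @export
chi_square_rates <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2
  n <- a + b + c + d
  if ((a + c) == 0 || (b + d) == 0)
    stop("chi-square undefined: a margin of the 2x2 table is zero")
  delta <- abs(a * d - b * c)
  if (correct) delta <- max(delta - n / 2, 0)
  chi2 <- n * delta^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Intra- and inter-assay coefficient-of-variance QC
#'
#' Reproduces the replicate quality-control computation: for each
#' target m/z, the matched detected peak's position and normalized
#' height are collected across replicate spectra of one reference
#' serum; the mass CV and intensity CV (SD/mean, percent) are computed
#' within each chip and averaged (intra-assay) and across all
#' replicates pooled over chips (inter-assay, undefined with a single
#' chip).  Reported CVs are averaged over the targets.
#'
#' @param replicates A [seldi_cohort()] of replicate spectra (already
#'   preprocessed, or raw with `preprocess = TRUE`).
#' @param target_mzs Numeric vector of target peak positions (the
#'   published QC used three peaks between m/z 3,000 and 10,000).
#' @param config A [pipeline_config()].
#' @param preprocess Preprocess the cohort first.
#' @return A list of class `qc_report`: `cv_mass_intra`,
#'   `cv_mass_inter`, `cv_intensity_intra`, `cv_intensity_inter` (all
#'   percent, `NA` when undefined), `n_replicates`, `n_chips`,
#'   `per_target` detail table.
#' @export
qc_cv <- function(replicates, target_mzs, config = pipeline_config(),
                  preprocess = TRUE) {
  stopifnot(inherits(replicates, "seldi_cohort"), length(target_mzs) >= 1)
  if (length(replicates$spectra) < 2) stop("need at least two replicates")
  if (preprocess) replicates <- preprocess_cohort(replicates, config)
  chips <- vapply(replicates$spectra, function(s) s$chip_id, character(1))
  n_chips <- length(unique(chips))
  half <- config$cluster_window / 2
  rows <- list()
  for (tm in target_mzs) {
    for (i in seq_along(replicates$spectra)) {
      s <- replicates$spectra[[i]]
      pk <- detect_peaks(s, snr_min = config$snr_second_pass,
                         noise_window = config$noise_window)
      hit <- which(abs(pk$mz - tm) <= half * tm)
      if (!length(hit)) {
        message("QC target m/z ", tm, " undetected in replicate ",
                s$sample_id, "; replicate excluded for this target")
        next
      }
      hit <- hit[which.max(pk$height[hit])]
      rows[[length(rows) + 1L]] <- data.frame(
        target = tm, chip = chips[i], sample_id = s$sample_id,
        mz = pk$mz[hit], height = pk$height[hit])
    }
  }
  if (!length(rows)) stop("no QC target detected in any replicate")
  tab <- do.call(rbind, rows)
  pct_cv <- function(x) if (length(x) >= 2 && mean(x) > 0)
    100 * stats::sd(x) / mean(x) else NA_real_
  per_target <- lapply(split(tab, tab$target), function(d) {
    by_chip_mass <- vapply(split(d$mz, d$chip), pct_cv, numeric(1))
    by_chip_int <- vapply(split(d$height, d$chip), pct_cv, numeric(1))
    data.frame(target = d$target[1],
               cv_mass_intra = mean(by_chip_mass, na.rm = TRUE),
               cv_intensity_intra = mean(by_chip_int, na.rm = TRUE),
               cv_mass_inter = if (n_chips >= 2) pct_cv(d$mz) else NA_real_,
               cv_intensity_inter = if (n_chips >= 2) pct_cv(d$height)
                                    else NA_real_)
  })
  per_target <- do.call(rbind, per_target)
  structure(list(
    cv_mass_intra = mean(per_target$cv_mass_intra, na.rm = TRUE),
    cv_mass_inter = mean(per_target$cv_mass_inter),
    cv_intensity_intra = mean(per_target$cv_intensity_intra, na.rm = TRUE),
    cv_intensity_inter = mean(per_target$cv_intensity_inter),
    n_replicates = length(replicates$spectra), n_chips = n_chips,
    per_target = per_target), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d replicates on %d chip(s)\n",
                     "  mass CV:      intra %.3f%%  inter %s%%\n",
                     "  intensity CV: intra %.2f%%  inter %s%%\n"),
              x$n_replicates, x$n_chips, x$cv_mass_intra,
              formatC(x$cv_mass_inter), x$cv_intensity_intra,
              formatC(x$cv_intensity_inter)))
  invisible(x)
}
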