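test_that("noise estimator: Gaussian calibration, zero case, peak robustness", {
  mz <- 2000:7000
  s <- withr::with_seed(3, seldi_spectrum(mz, abs(rnorm(5001, 5, 0.5))))
  noise <- estimate_noise(s)
  expect_equal(median(noise), 0.5, tolerance = 0.1)

  zero <- seldi_spectrum(mz, rep(0, 5001))
  expect_true(all(estimate_noise(zero) == 0))

  # adding one isolated narrow peak moves the estimate < 10%
  y <- s$intensity + 50 * exp(-(mz - 4500)^2 / (2 * 3^2))
  noise2 <- estimate_noise(seldi_spectrum(mz, y))
  expect_equal(median(noise2), median(noise), tolerance = 0.1)
  expect_error(estimate_noise(s, window_points = 5), "11")
})

test_that("peak detection: construction oracles and Monte-Carlo miss rate", {
  # tiny acquisition window around one planted peak, preprocessed as in
  # the pipeline (detect_peaks expects preprocessed spectra)
  peaks <- data.frame(mz = 4497, mean_pos = 0.1, sd_pos = 0, mean_neg = 0.1,
                      sd_neg = 0, differential = FALSE)
  cfg <- generator_config(peaks = peaks, grid_min = 4000, grid_max = 5000,
                          noise_sd = 0.01, mass_jitter_cv = 0,
                          intensity_cv = 0)
  one <- function(height, seed) {
    s <- withr::with_seed(seed, render_spectrum(
      stats::setNames(height, "4497"), cfg))
    detect_peaks(window_mz(subtract_baseline(s, 100), 4100, 4900),
                 snr_min = 3)
  }
  # single peak at 10x noise: exactly one detection within 2 grid steps
  hits <- 0
  for (seed in 1:10) {
    pk <- one(0.1, seed)
    if (nrow(pk) == 1 && abs(pk$mz - 4497) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # peak at 1x noise with snr_min = 3: not detected in >= 90% of 50 seeds
  miss <- 0
  for (seed in 1:50) {
    if (!any(abs(one(0.01, seed)$mz - 4497) <= 5)) miss <- miss + 1
  }
  expect_gte(miss, 45)

  zero <- seldi_spectrum(2000:4000, rep(0, 2001))
  expect_equal(nrow(detect_peaks(zero)), 0)

  # monotonicity: a stricter S/N threshold returns a subset
  cfg2 <- small_gen_config(noise_sd = 0.01, mass_jitter_cv = 0,
                           intensity_cv = 0)
  s <- withr::with_seed(1, render_spectrum(c(`3104` = 0.05, `4497` = 1), cfg2))
  s <- window_mz(subtract_baseline(s, 200), 2000, 8000)
  lo <- detect_peaks(s, snr_min = 2)
  hi <- detect_peaks(s, snr_min = 6)
  expect_true(all(hi$mz %in% lo$mz))
  expect_true(all(detect_peaks(s, snr_min = 3)$snr >= 3))
})

test_that("first-pass filter: threshold arithmetic and drift tolerance", {
  mk_peaks <- function(n_with, mz, n_spectra = 145) {
    do.call(rbind, lapply(seq_len(n_with), function(i)
      data.frame(mz = mz, height = 1, snr = 5,
                 sample_id = sprintf("s%03d", i))))
  }
  # present in 30 of 145 spectra (20.7%): retained; in 28 (19.3%): dropped
  res30 <- first_pass_filter(mk_peaks(30, 5000), n_spectra = 145)
  expect_equal(nrow(res30$clusters), 1)
  res28 <- first_pass_filter(mk_peaks(28, 5000), n_spectra = 145)
  expect_equal(nrow(res28$clusters), 0)

  # min_fraction = 0 retains everything
  one <- data.frame(mz = c(3000, 9000), height = 1, snr = 5, sample_id = "a")
  expect_equal(nrow(first_pass_filter(one, 145, min_fraction = 0)$clusters), 2)

  # a peak drifting +/- 0.2% of m/z clusters once at window 0.5%
  drift <- do.call(rbind, lapply(1:50, function(i)
    data.frame(mz = 8000 * (1 + 0.002 * sin(i)), height = 1, snr = 5,
               sample_id = sprintf("s%03d", i))))
  res <- first_pass_filter(drift, n_spectra = 145)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$prevalence, 50 / 145)
})

test_that("two-pass matrix: completeness, windows, planted-cluster identity", {
  cfg <- small_gen_config()
  coh <- generate_cohort(cfg, 8, 8, seed = 11)
  pp <- preprocess_cohort(coh, pipeline_config(mz_max = 8000))
  pm <- build_peak_matrix(pp, pipeline_config(mz_max = 8000))
  expect_equal(ncol(pm$values), nrow(cfg$peaks))
  expect_true(all(is.finite(pm$values)))
  # non-overlapping windows covering each centre
  cl <- pm$clusters
  expect_true(all(cl$window_hi[-nrow(cl)] <= cl$window_lo[-1] + 1e-9))
  expect_true(all(cl$mz_center > cl$window_lo & cl$mz_center < cl$window_hi))
  # every planted peak maps to exactly one cluster within 0.25%
  d <- vapply(cfg$peaks$mz, function(p) min(abs(cl$mz_center - p) / p), 1)
  expect_true(all(d < 0.0025))

  # a spectrum missing one peak gets the flagged window maximum
  fv <- cfg$peaks$mean_pos
  names(fv) <- as.character(cfg$peaks$mz)
  cfg0 <- small_gen_config(noise_sd = 0.005, mass_jitter_cv = 0,
                           intensity_cv = 0)
  full <- lapply(1:5, function(i) withr::with_seed(
    i, render_spectrum(fv, cfg0, sample_id = paste0("f", i),
                       label = "node_positive")))
  fv0 <- fv; fv0[["5867"]] <- 0
  hole <- withr::with_seed(99, render_spectrum(
    fv0, cfg0, sample_id = "hole", label = "node_negative"))
  pp2 <- preprocess_cohort(seldi_cohort(c(full, list(hole))),
                           pipeline_config(mz_max = 8000))
  pm2 <- build_peak_matrix(pp2, pipeline_config(mz_max = 8000))
  j <- which.min(abs(pm2$clusters$mz_center - 5867))
  expect_true(pm2$flags["hole", j])
  expect_lt(pm2$values["hole", j], 0.1)
  expect_false(any(pm2$flags[paste0("f", 1:5), j]))
})

test_that("default world yields 46 clusters across seeds", {
  cfg <- generator_config()
  for (seed in 1:10) {
    coh <- generate_cohort(cfg, 70, 75, seed = seed)
    pm <- build_peak_matrix(preprocess_cohort(coh))
    expect_equal(ncol(pm$values), 46)
  }
})

test_that("peak matrix CSV round-trip", {
  cfg <- small_gen_config()
  pm <- generate_feature_matrix(cfg, 3, 3, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_peak_matrix(pm, f)
  pm2 <- read_peak_matrix(f)
  expect_equal(pm2$values, pm$values, tolerance = 1e-9)
  expect_equal(pm2$labels, pm$labels)
  expect_equal(pm2$clusters$mz_center, pm$clusters$mz_center)
})
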