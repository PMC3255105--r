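test_that("differential peak panel matches the published values", {
  p <- differential_peak_panel()
  expect_equal(nrow(p), 22)
  expect_true(all(p$differential))
  r <- p[p$mz == 5867, ]
  expect_equal(unlist(r[c("mean_pos", "sd_pos", "mean_neg", "sd_neg")]),
               c(mean_pos = 3.534, sd_pos = 0.547,
                 mean_neg = 0.230, sd_neg = 0.107))
  r <- p[p$mz == 3104, ]
  expect_equal(r$mean_pos, 4.719)
  expect_equal(r$mean_neg, 6.626)
  # hand count of peaks elevated in the node-positive class
  expect_equal(sum(p$mean_pos > p$mean_neg), 13)
})

test_that("generator configuration invariants", {
  cfg <- generator_config()
  expect_equal(nrow(cfg$peaks), 46)
  expect_equal(sum(cfg$peaks$differential), 22)
  # nuisance peaks carry no class signal and sit > 1% from each other
  nuis <- cfg$peaks[!cfg$peaks$differential, ]
  expect_equal(nuis$mean_pos, nuis$mean_neg)
  expect_true(all(diff(sort(nuis$mz)) / sort(nuis$mz)[-1] > 0.01))
  # peaks inside each other's half cluster window are rejected
  bad <- data.frame(mz = c(5000, 5005), mean_pos = 1, sd_pos = 0,
                    mean_neg = 1, sd_neg = 0, differential = FALSE)
  expect_error(generator_config(peaks = bad), "1:1")
})

test_that("feature vectors: zero-variance limit, moments, nonnegativity", {
  cfg <- generator_config()
  frozen <- frozen_gen_config()
  fv <- withr::with_seed(1, sample_feature_vector(frozen, "node_positive"))
  expect_equal(unname(fv), cfg$peaks$mean_pos)

  draws <- withr::with_seed(7, replicate(
    10000, sample_feature_vector(cfg, "node_negative")))
  expect_true(all(draws >= 0))
  # per-peak sample mean close to the configured mean (4-SE band so the
  # 46 simultaneous comparisons are not flaky; + small censoring shift)
  m <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(m - cfg$peaks$mean_neg) < 4 * se + 2e-3))
  # smallest panel peak (m/z 7,504 node-positive) never goes negative
  pos <- withr::with_seed(8, replicate(
    10000, sample_feature_vector(cfg, "node_positive")["7504"]))
  expect_true(all(pos >= 0))
})

test_that("rendering: degenerate inputs and apex placement", {
  cfg <- small_gen_config(noise_sd = 0, baseline_amplitude = 0,
                          mass_jitter_cv = 0, intensity_cv = 0)
  s0 <- withr::with_seed(1, render_spectrum(numeric(0), cfg))
  expect_true(all(s0$intensity == 0))
  fv <- c(`4497` = 5)
  s1 <- withr::with_seed(1, render_spectrum(fv, cfg))
  expect_equal(s1$mz[which.max(s1$intensity)], 4497)
  expect_equal(max(s1$intensity), 5, tolerance = 1e-6)
  expect_error(render_spectrum(c(`500` = 1), cfg), "inside the acquisition")
})

test_that("zero-variance world reproduces the panel means end to end", {
  cfg <- frozen_gen_config()
  coh <- generate_cohort(cfg, 2, 2, seed = 3)
  pm <- build_peak_matrix(preprocess_cohort(coh))
  expect_equal(ncol(pm$values), 46)
  got_pos <- as.numeric(pm$values[1, ])
  got_neg <- as.numeric(pm$values[3, ])
  expect_equal(got_pos, cfg$peaks$mean_pos, tolerance = 0.05)
  # node-negative means, skipping the one peak below the detection floor
  big <- cfg$peaks$mean_neg > 0.1
  expect_equal(got_neg[big], cfg$peaks$mean_neg[big], tolerance = 0.05)
})

test_that("planted-peak recovery within 5% at default noise", {
  cfg <- generator_config()
  cfg$peaks$sd_pos <- 0
  cfg$peaks$sd_neg <- 0
  cfg <- generator_config(peaks = cfg$peaks, intensity_cv = 0,
                          chip_intensity_cv = 0)
  coh <- generate_cohort(cfg, 3, 3, seed = 9)
  pm <- build_peak_matrix(preprocess_cohort(coh))
  strong <- cfg$peaks$mean_pos >= 5 * cfg$noise_sd
  rel <- sweep(pm$values[1:3, strong, drop = FALSE], 2,
               cfg$peaks$mean_pos[strong], "/") - 1
  expect_lt(max(abs(rel)), 0.05)
})

test_that("cohort generation: sizes, chips, determinism, empty case", {
  cfg <- small_gen_config()
  coh <- generate_cohort(cfg, 7, 8, seed = 2)
  labs <- vapply(coh$spectra, `[[`, "", "label")
  expect_length(coh, 15)
  expect_equal(sum(labs == "node_positive"), 7)
  expect_equal(vapply(coh$spectra[1:3], `[[`, "", "chip_id"),
               c("chip01", "chip02", "chip03"))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, 3, 2, seed = 4, out_dir = d1)
  generate_cohort(cfg, 3, 2, seed = 4, out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  expect_length(generate_cohort(cfg, 0, 0, seed = 1), 0)
})

test_that("qc replicates: degenerate determinism and chip structure", {
  cfg <- frozen_gen_config()
  qc <- generate_qc_replicates(cfg, n_per_chip = 3, n_chips = 2, seed = 6)
  expect_length(qc, 6)
  expect_equal(qc$role, "qc_replicates")
  # jitter and intensity CV zero => identical replicate traces
  expect_identical(qc$spectra[[1]]$intensity, qc$spectra[[6]]$intensity)
})

test_that("raising noise cannot rescue a weak peak from the S/N 3 criterion", {
  # monotone-noise property, checked statistically over seeds
  fails <- function(noise_sd) {
    cfg <- small_gen_config(noise_sd = noise_sd, mass_jitter_cv = 0,
                            intensity_cv = 0, chip_intensity_cv = 0)
    cfg$peaks$sd_pos <- 0; cfg$peaks$sd_neg <- 0
    cfg$peaks[cfg$peaks$mz == 5867, c("mean_pos", "mean_neg")] <- 0.12
    n_fail <- 0L
    for (seed in 1:6) {
      coh <- generate_cohort(cfg, 0, 1, seed = seed)
      s <- preprocess_cohort(coh)$spectra[[1]]
      pk <- detect_peaks(s, snr_min = 3)
      if (!any(abs(pk$mz - 5867) < 15)) n_fail <- n_fail + 1L
    }
    n_fail
  }
  expect_lte(fails(0.01), fails(0.08))
})
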