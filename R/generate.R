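#' Published differential serum peak panel
#'
#' The 22 serum protein peaks reported to differ between node-positive
#' and node-negative colorectal-cancer patients, as class-conditional
#' normalized-intensity means and standard deviations keyed by m/z.
#' These values parameterize the synthetic-spectrum generator; they are
#' the generator's ground truth, not measurements made by this package.
#'
#' @return A `data.frame` with columns `mz`, `mean_pos`, `sd_pos`,
#'   `mean_neg`, `sd_neg`, `differential` (all `TRUE`), sorted by
#'   ascending m/z.
#' @export
differential_peak_panel <- function() {
  p <- data.frame(
    mz       = c(5867, 9290, 7970, 14433, 15621, 15824, 13652, 3781, 15006,
                 7802, 4497, 7504, 5967, 5808, 10057, 7597, 5786, 15089,
                 3104, 14869, 7620, 5662),
    mean_pos = c(3.534, 3.271, 12.364, 0.891, 1.782, 0.729, 1.388, 4.268,
                 0.641, 6.580, 9.154, 0.034, 8.809, 4.947, 1.809, 44.557,
                 16.269, 0.708, 4.719, 1.922, 12.534, 1.760),
    sd_pos   = c(0.547, 0.587, 1.08, 0.168, 0.609, 0.111, 0.168, 0.216,
                 0.150, 0.504, 0.639, 0.005, 0.705, 0.797, 0.301, 1.121,
                 1.880, 0.198, 0.478, 0.653, 2.920, 0.601),
    mean_neg = c(0.230, 1.443, 7.913, 0.404, 5.873, 2.072, 2.423, 6.799,
                 1.824, 5.170, 5.139, 0.704, 6.021, 2.252, 1.206, 37.993,
                 11.966, 1.678, 6.626, 4.278, 8.908, 0.266),
    sd_neg   = c(0.107, 0.103, 0.668, 0.102, 0.655, 0.255, 0.259, 0.977,
                 0.084, 0.635, 0.916, 0.271, 0.879, 0.990, 0.245, 1.763,
                 0.994, 0.042, 0.791, 1.079, 1.474, 0.131))
  p$differential <- TRUE
  p[order(p$mz), , drop = FALSE]
}

#' Nuisance (non-differential) peak panel
#'
#' Synthetic stand-ins for the serum peaks that are present in every
#' spectrum but carry no class signal, bringing the planted total to the
#' 46 common peak clusters reported for the real training cohort.
#' Positions are spaced more than 1% apart and away from the
#' differential panel; intensities span the same range as the
#' differential panel with a 20% biological coefficient of variation.
#'
#' @return A `data.frame` in the same layout as
#'   [differential_peak_panel()] with `differential = FALSE` and equal
#'   class means.
#' @export
nuisance_peak_panel <- function() {
  mz <- c(2306, 2553, 2811, 3320, 3512, 4102, 4916, 5214, 6354, 6710,
          7118, 8437, 8843, 9654, 10482, 11095, 11738, 12419, 13120,
          16489, 17235, 18120, 19043, 19750)
  mean <- c(25, 32, 18, 12, 40, 22, 15, 9, 28, 11, 19, 24, 8, 14, 6, 10,
            5, 7, 12, 4, 3, 5, 2, 3)
  data.frame(mz = mz, mean_pos = mean, sd_pos = 0.2 * mean,
             mean_neg = mean, sd_neg = 0.2 * mean, differential = FALSE)
}

#' Synthetic-spectrum generator configuration
#'
#' Describes the stochastic world the generator emulates: planted peaks
#' (class-conditional truncated-normal intensities), a uniform m/z
#' grid, Gaussian peak shapes whose width scales with m/z, an
#' exponentially decaying chemical baseline, additive detector noise,
#' a per-spectrum mass-calibration jitter of 0.03% and a per-peak
#' technical intensity error of 17% (plus a 9% between-chip
#' component, so that total between-chip variation matches the
#' reported 19.5% inter-assay CV).
#'
#' @param peaks `data.frame` of planted peaks (see
#'   [differential_peak_panel()]); defaults to the 22 differential plus
#'   24 nuisance peaks (46 total).
#' @param grid_min,grid_max,grid_step m/z acquisition grid in Da.
#' @param peak_width_fraction Gaussian sigma as a fraction of the peak
#'   m/z (0.0008 corresponds to a mass resolution of roughly 530
#'   FWHM, enough to resolve the closest published peak pair, 0.3%
#'   apart).
#' @param baseline_amplitude,baseline_decay Exponential baseline
#'   `A * exp(-(mz - grid_min)/decay)`, highest at low m/z (matrix
#'   noise of the energy-absorbing molecule).
#' @param noise_sd Additive Gaussian noise standard deviation, in
#'   normalized-intensity units.
#' @param mass_jitter_cv Standard deviation of the per-spectrum
#'   fractional m/z perturbation (0.0003 = 0.03%).
#' @param intensity_cv Per-peak multiplicative technical intensity error
#'   (0.17 = 17% intra-assay CV).
#' @param chip_intensity_cv Additional per-chip multiplicative intensity
#'   component (0.09 so that sqrt(0.17^2 + 0.09^2) matches the 19.5%
#'   inter-assay CV).
#' @param n_chips Number of protein-chip arrays spectra are assigned to,
#'   round-robin.
#' @param cluster_window Fractional mass window used only to validate
#'   that planted peaks are separable into distinct clusters.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(peaks = NULL, grid_min = 1000, grid_max = 20000,
                             grid_step = 1, peak_width_fraction = 0.0008,
                             baseline_amplitude = 30, baseline_decay = 3000,
                             noise_sd = 0.01, mass_jitter_cv = 0.0003,
                             intensity_cv = 0.17, chip_intensity_cv = 0.09,
                             n_chips = 31L, cluster_window = 0.005) {
  if (is.null(peaks))
    peaks <- rbind(differential_peak_panel(), nuisance_peak_panel())
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  stopifnot(all(peaks$sd_pos >= 0), all(peaks$sd_neg >= 0))
  if (any(peaks$mz < grid_min | peaks$mz > grid_max))
    stop("planted peak m/z outside the acquisition grid")
  sep <- diff(peaks$mz) / peaks$mz[-1]
  if (any(sep <= cluster_window / 2))
    stop("planted peaks closer than half the cluster window cannot map ",
         "1:1 to clusters")
  structure(list(peaks = peaks, grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step,
                 peak_width_fraction = peak_width_fraction,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay, noise_sd = noise_sd,
                 mass_jitter_cv = mass_jitter_cv, intensity_cv = intensity_cv,
                 chip_intensity_cv = chip_intensity_cv,
                 n_chips = as.integer(n_chips),
                 cluster_window = cluster_window),
            class = "generator_config")
}

generator_grid <- function(config) {
  seq(config$grid_min, config$grid_max, by = config$grid_step)
}

#' Draw one class-conditional peak feature vector
#'
#' Each planted peak's intensity is drawn independently from
#' `Normal(mean_class, sd_class)` and censored at zero (negative draws
#' are set to 0); nuisance peaks use their class-independent mean.
#' Uses the current RNG stream; wrap in a seeded context for
#' reproducibility.
#'
#' @param config A [generator_config()].
#' @param label `"node_positive"` or `"node_negative"`.
#' @return Named numeric vector (names = peak m/z) of intensities.
#' @export
sample_feature_vector <- function(config, label) {
  label <- match.arg(label, c("node_positive", "node_negative"))
  p <- config$peaks
  m <- if (label == "node_positive") p$mean_pos else p$mean_neg
  s <- if (label == "node_positive") p$sd_pos else p$sd_neg
  x <- pmax(stats::rnorm(nrow(p), m, s), 0)
  names(x) <- as.character(p$mz)
  x
}

#' Render a feature vector as a full synthetic spectrum
#'
#' Builds `baseline(mz) + sum_p A_p * Gaussian(mz; c_p * (1 + jitter),
#' sigma_p) + noise`, clipped at zero.  `A_p` is the feature value times
#' the technical intensity error and (if given) the chip effect, so the
#' rendered apex height equals the feature value up to those errors.
#'
#' @param features Named numeric vector, names = peak m/z in Da (must
#'   lie on/inside the grid).
#' @param config A [generator_config()].
#' @param sample_id,label,chip_id Spectrum metadata.
#' @param chip_effect Optional numeric vector (one multiplier per peak)
#'   representing the chip-level intensity component.
#' @return A [seldi_spectrum()] on the configured grid.
#' @export
render_spectrum <- function(features, config, sample_id = "sample",
                            label = "unlabelled", chip_id = "chip01",
                            chip_effect = NULL) {
  grid <- generator_grid(config)
  centers <- as.numeric(names(features))
  if (length(features) && (any(centers < config$grid_min) ||
                           any(centers > config$grid_max)))
    stop("feature m/z centres must lie inside the acquisition grid")
  n <- length(grid)
  jitter <- if (config$mass_jitter_cv > 0)
    stats::rnorm(1, 0, config$mass_jitter_cv) else 0
  tech <- if (config$intensity_cv > 0)
    pmax(stats::rnorm(length(features), 1, config$intensity_cv), 0)
  else rep(1, length(features))
  if (is.null(chip_effect)) chip_effect <- rep(1, length(features))
  y <- config$baseline_amplitude *
    exp(-(grid - config$grid_min) / config$baseline_decay)
  for (p in seq_along(features)) {
    a <- features[[p]] * tech[p] * chip_effect[p]
    if (a <= 0) next
    cj <- centers[p] * (1 + jitter)
    sigma <- config$peak_width_fraction * centers[p]
    lo <- max(1L, ceiling((cj - 6 * sigma - config$grid_min) / config$grid_step) + 1L)
    hi <- min(n, floor((cj + 6 * sigma - config$grid_min) / config$grid_step) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    y[idx] <- y[idx] + a * exp(-(grid[idx] - cj)^2 / (2 * sigma^2))
  }
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(n, 0, config$noise_sd)
  seldi_spectrum(grid, pmax(y, 0), sample_id = sample_id, label = label,
                 chip_id = chip_id)
}

#' Generate a synthetic cohort of spectra
#'
#' Draws `n_pos + n_neg` class-conditional feature vectors and renders
#' each as a full spectrum; chips are assigned round-robin over
#' `config$n_chips` arrays.  Fully deterministic given `seed`.
#' Defaults mirror the published cohort sizes (70/75 training,
#' 35/30 blind test).
#'
#' @param config A [generator_config()].
#' @param n_pos,n_neg Numbers of node-positive / node-negative samples.
#' @param role Cohort role (also used as the sample-id prefix).
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, spectra and a manifest are also written
#'   there via [write_cohort()].
#' @return A [seldi_cohort()].
#' @export
generate_cohort <- function(config, n_pos = 70L, n_neg = 75L,
                            role = c("training", "test", "qc_replicates"),
                            seed = 1L, out_dir = NULL) {
  role <- match.arg(role)
  prefix <- c(training = "TR", test = "TS", qc_replicates = "QC")[[role]]
  npk <- nrow(config$peaks)
  cohort <- with_seed(seed, {
    chip_fx <- matrix(pmax(stats::rnorm(config$n_chips * npk, 1,
                                        config$chip_intensity_cv), 0),
                      nrow = config$n_chips)
    labels <- rep(c("node_positive", "node_negative"), c(n_pos, n_neg))
    spectra <- vector("list", n_pos + n_neg)
    for (i in seq_along(spectra)) {
      chip <- (i - 1L) %% config$n_chips + 1L
      fv <- sample_feature_vector(config, labels[i])
      spectra[[i]] <- render_spectrum(
        fv, config, sample_id = sprintf("%s%03d", prefix, i),
        label = labels[i], chip_id = sprintf("chip%02d", chip),
        chip_effect = chip_fx[chip, ])
    }
    spectra
  })
  cohort <- seldi_cohort(cohort, role = role)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Generate a peak matrix directly (no spectrum rendering)
#'
#' Bypasses rendering/preprocessing/detection and returns the sampled
#' class-conditional feature vectors as a complete [peak_matrix()] --
#' the `--matrix-only` path used for classifier-level experiments,
#' where the published class-conditional distributions themselves are
#' the data-generating model.
#'
#' @inheritParams generate_cohort
#' @param differential_only If `TRUE`, restrict to the 22 differential
#'   panel peaks.
#' @return A [peak_matrix()].
#' @export
generate_feature_matrix <- function(config, n_pos = 70L, n_neg = 75L,
                                    seed = 1L, differential_only = FALSE) {
  if (differential_only) {
    config <- generator_config(
      peaks = config$peaks[config$peaks$differential, , drop = FALSE],
      grid_min = config$grid_min, grid_max = config$grid_max,
      cluster_window = config$cluster_window)
  }
  labels <- rep(c("node_positive", "node_negative"), c(n_pos, n_neg))
  vals <- with_seed(seed, t(vapply(labels, function(lb)
    sample_feature_vector(config, lb), numeric(nrow(config$peaks)))))
  rownames(vals) <- sprintf("S%03d", seq_along(labels))
  mz <- config$peaks$mz
  clusters <- data.frame(cluster_id = seq_along(mz), mz_center = mz,
                         window_lo = mz * (1 - config$cluster_window / 2),
                         window_hi = mz * (1 + config$cluster_window / 2),
                         prevalence = 1)
  peak_matrix(vals, clusters, labels)
}

#' Generate replicate spectra of one reference serum
#'
#' Emulates the quality-control design: one fixed feature vector (the
#' pooled per-peak mean, standing in for the healthy-volunteer serum)
#' rendered repeatedly, `n_per_chip` times on each of `n_chips` chips.
#' Within-chip spread is governed by `intensity_cv` and
#' `mass_jitter_cv`; the chip effect adds the between-chip component.
#'
#' @param config A [generator_config()].
#' @param n_per_chip,n_chips Replicates per chip and number of chips
#'   (both >= 1; with a single chip the inter-assay CV is undefined
#'   downstream).
#' @param seed Integer seed.
#' @return A [seldi_cohort()] with role `"qc_replicates"`.
#' @export
generate_qc_replicates <- function(config, n_per_chip = 5L, n_chips = 5L,
                                   seed = 1L) {
  stopifnot(n_per_chip >= 1, n_chips >= 1)
  p <- config$peaks
  ref <- (p$mean_pos + p$mean_neg) / 2
  names(ref) <- as.character(p$mz)
  spectra <- with_seed(seed, {
    chip_fx <- matrix(pmax(stats::rnorm(n_chips * nrow(p), 1,
                                        config$chip_intensity_cv), 0),
                      nrow = n_chips)
    out <- vector("list", n_per_chip * n_chips)
    k <- 0L
    for (chip in seq_len(n_chips)) {
      for (r in seq_len(n_per_chip)) {
        k <- k + 1L
        out[[k]] <- render_spectrum(
          ref, config, sample_id = sprintf("QC%02d_%02d", chip, r),
          label = "unlabelled", chip_id = sprintf("chip%02d", chip),
          chip_effect = chip_fx[chip, ])
      }
    }
    out
  })
  seldi_cohort(spectra, role = "qc_replicates")
}
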