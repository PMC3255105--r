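# Shared fixtures: everything is generated in code at test time.

# Small, fast generator world (reduced grid) for render-level tests
# where only the property under test, not the cohort geometry, matters.
small_gen_config <- function(...) {
  peaks <- data.frame(mz = c(2500, 3104, 4497, 5867, 7000),
                      mean_pos = c(10, 4.719, 9.154, 3.534, 20),
                      sd_pos = c(2, 0.478, 0.639, 0.547, 4),
                      mean_neg = c(10, 6.626, 5.139, 0.230, 20),
                      sd_neg = c(2, 0.791, 0.916, 0.107, 4),
                      differential = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  generator_config(peaks = peaks, grid_min = 1000, grid_max = 8000, ...)
}

# Deterministic, noiseless world: every draw equals the class mean.
frozen_gen_config <- function(base = generator_config(), noise_sd = 0) {
  cfg <- generator_config(peaks = base$peaks, grid_min = base$grid_min,
                          grid_max = base$grid_max,
                          peak_width_fraction = base$peak_width_fraction,
                          baseline_amplitude = base$baseline_amplitude,
                          baseline_decay = base$baseline_decay,
                          noise_sd = noise_sd, mass_jitter_cv = 0,
                          intensity_cv = 0, chip_intensity_cv = 0)
  cfg$peaks$sd_pos <- 0
  cfg$peaks$sd_neg <- 0
  cfg
}

# Published class-conditional mean vectors over the 22-panel peaks.
panel_mean_vector <- function(class = c("node_positive", "node_negative")) {
  class <- match.arg(class)
  p <- differential_peak_panel()
  x <- if (class == "node_positive") p$mean_pos else p$mean_neg
  m <- matrix(x, nrow = 1, dimnames = list("m", paste0("mz_", p$mz)))
  m
}

# Brute-force oracle: best Gini split of a 1-D feature by enumerating
# every midpoint between consecutive sorted values.
enum_axis_oracle <- function(x, y) {
  xs <- sort(unique(x))
  gini <- function(lab) {
    p <- table(lab) / length(lab)
    1 - sum(p^2)
  }
  parent <- gini(y)
  best <- list(threshold = NA_real_, decrease = 0)
  if (length(xs) < 2) return(best)
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    l <- y[x <= thr]; r <- y[x > thr]
    dec <- parent - length(l) / length(y) * gini(l) -
      length(r) / length(y) * gini(r)
    if (dec > best$decrease + 1e-15) best <- list(threshold = thr, decrease = dec)
  }
  best
}

# Brute-force oracle for 2-feature oblique splits: dense grid over
# direction angles, exact best threshold per direction.
grid_oblique_oracle <- function(x, y, n_angles = 4000) {
  best <- 0
  for (theta in seq(0, pi, length.out = n_angles)) {
    z <- x[, 1] * cos(theta) + x[, 2] * sin(theta)
    dec <- enum_axis_oracle(z, y)$decrease
    if (dec > best) best <- dec
  }
  best
}
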