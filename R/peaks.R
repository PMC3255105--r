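#' Local noise level of a spectrum
#'
#' `noise(x)` is 1.4826 times the median absolute deviation of the
#' detrended intensity (intensity minus a running median) computed in
#' centred sliding windows of `window_points` points.  For Gaussian
#' noise this recovers the noise standard deviation; the median makes
#' the estimate robust to isolated peaks.
#'
#' @param s A [seldi_spectrum()] (typically preprocessed).
#' @param window_points Window size in points (>= 11).
#' @return Numeric vector of per-point noise levels.
#' @export
estimate_noise <- function(s, window_points = 151L) {
  stopifnot(inherits(s, "seldi_spectrum"), window_points >= 11)
  noise_profile(s$intensity, window_points)
}

noise_profile <- function(y, window_points) {
  n <- length(y)
  k <- min(make_odd(window_points), make_odd(n - 1L))
  med <- stats::runmed(y, k, endrule = "median")
  resid <- abs(y - med)
  w <- as.integer(window_points)
  nb <- ceiling(n / w)
  pad <- c(resid, rep(NA_real_, nb * w - n))
  blocks <- matrix(pad, nrow = w)
  bmad <- 1.4826 * apply(blocks, 2L, stats::median, na.rm = TRUE)
  centers <- (seq_len(nb) - 0.5) * w
  if (nb == 1L) return(rep(bmad, n))
  # peaks can only inflate a block's MAD and true noise varies slowly,
  # so take the minimum over each block and its neighbours
  bmad <- pmin(bmad, c(bmad[-1L], Inf), c(Inf, bmad[-nb]))
  stats::approx(centers, bmad, xout = seq_len(n), rule = 2)$y
}

# Shared per-spectrum detection state: lightly smoothed trace, running
# median (local height reference), and the raw-trace noise profile
# (the "visible" noise amplitude the S/N criterion is quoted against).
detection_state <- function(s, noise_window = 151L, median_window = 601L) {
  y <- s$intensity
  n <- length(y)
  ys <- roll_mean(y, 2L)                       # 5-point smoothing
  # the height-reference window is wide enough that even the densest
  # group of planted peaks covers less than half of it
  k <- min(make_odd(median_window), make_odd(n - 1L))
  med <- stats::runmed(ys, k, endrule = "median")
  list(mz = s$mz, y = y, ys = ys, med = med,
       noise = noise_profile(y, noise_window))
}

#' Detect peaks in a single spectrum
#'
#' Peaks are local maxima of a lightly smoothed trace whose height
#' above the local running median exceeds `snr_min` times the local
#' noise level; maxima closer together than a resolution-scaled
#' neighbourhood are merged into the higher one.  Reported heights are
#' apex intensities above the local median, taken from the unsmoothed
#' trace.
#'
#' @param s A preprocessed [seldi_spectrum()].
#' @param snr_min Minimum signal-to-noise ratio (first pass uses 3).
#' @param noise_window Noise-estimator window in points.
#' @param sigma_fraction Assumed instrument peak sigma as a fraction of
#'   m/z; sets the merge neighbourhood (1.5 sigma).
#' @return `data.frame` with columns `mz`, `height`, `snr`, `index`,
#'   `sample_id`, sorted by ascending m/z.
#' @export
detect_peaks <- function(s, snr_min = 3, noise_window = 151L,
                         sigma_fraction = 0.0008) {
  st <- detection_state(s, noise_window)
  detect_peaks_state(st, snr_min, sigma_fraction, s$sample_id)
}

detect_peaks_state <- function(st, snr_min, sigma_fraction, sample_id) {
  ys <- st$ys; y <- st$y; med <- st$med; noise <- st$noise
  n <- length(ys)
  empty <- data.frame(mz = numeric(0), height = numeric(0), snr = numeric(0),
                      index = integer(0), sample_id = character(0))
  if (n < 3L) return(empty)
  i <- 2:(n - 1L)
  cand <- i[ys[i] > ys[i - 1L] & ys[i] >= ys[i + 1L]]
  if (!length(cand)) return(empty)
  hs <- pmax(ys[cand] - med[cand], 0)
  snr <- ifelse(noise[cand] > 0, hs / noise[cand],
                ifelse(hs > 0, Inf, 0))
  keep <- snr >= snr_min & hs > 0
  cand <- cand[keep]; hs <- hs[keep]; snr <- snr[keep]
  if (!length(cand)) return(empty)
  # non-maximum suppression within 1.5 assumed peak sigmas
  step <- if (n > 1L) (st$mz[n] - st$mz[1L]) / (n - 1L) else 1
  width <- pmax(4L, as.integer(round(1.5 * sigma_fraction * st$mz[cand] / step)))
  ord <- order(-hs, st$mz[cand])
  kept <- logical(length(cand))
  taken_idx <- integer(0)
  taken_w <- integer(0)
  for (j in ord) {
    if (length(taken_idx) &&
        any(abs(taken_idx - cand[j]) <= pmax(taken_w, width[j]))) next
    kept[j] <- TRUE
    taken_idx <- c(taken_idx, cand[j])
    taken_w <- c(taken_w, width[j])
  }
  cand <- cand[kept]; snr <- snr[kept]
  # apex on the unsmoothed trace, within +/- 2 points of the smoothed apex
  apex <- vapply(cand, function(i0) {
    lo <- max(1L, i0 - 2L); hi <- min(n, i0 + 2L)
    lo + which.max(ys[lo:hi]) - 1L
  }, integer(1))
  height <- pmax(y[apex] - med[apex], 0)
  out <- data.frame(mz = st$mz[apex], height = height, snr = snr,
                    index = apex, sample_id = sample_id,
                    stringsAsFactors = FALSE)
  out[order(out$mz), , drop = FALSE]
}

#' First-pass filter: provisional peak clusters by prevalence
#'
#' Greedily agglomerates first-pass peaks from all spectra into
#' provisional clusters within the fractional mass window (seeds chosen
#' by descending peak support, ties broken by ascending m/z; at most
#' one member peak per spectrum per cluster, the one closest to the
#' seed), then retains the clusters whose members come from at least
#' `min_fraction` of the spectra.
#'
#' @param peaks Either a list of per-spectrum `data.frame`s from
#'   [detect_peaks()] or one combined `data.frame`.
#' @param n_spectra Total number of spectra peaks were detected in.
#' @param min_fraction Minimum fraction of spectra (the published
#'   minimum peak threshold is 20%).
#' @param cluster_window Total fractional mass window (0.005 = 0.5%,
#'   i.e. +/- 0.25% around the seed).
#' @return A list with `clusters` (`data.frame`: `cluster_id`,
#'   `mz_center`, `prevalence`) and `members` (per-peak assignment
#'   table), clusters sorted by ascending centre.
#' @export
first_pass_filter <- function(peaks, n_spectra, min_fraction = 0.20,
                              cluster_window = 0.005) {
  if (is.data.frame(peaks)) pk <- peaks else pk <- do.call(rbind, peaks)
  if (is.null(pk) || !nrow(pk))
    return(list(clusters = data.frame(cluster_id = integer(0),
                                      mz_center = numeric(0),
                                      prevalence = numeric(0)),
                members = data.frame()))
  pk <- pk[order(pk$mz), , drop = FALSE]
  half <- cluster_window / 2
  m <- pk$mz
  unassigned <- rep(TRUE, nrow(pk))
  cluster_of <- rep(NA_integer_, nrow(pk))
  centers <- numeric(0)
  prevalence <- numeric(0)
  min_members <- max(1, min_fraction * n_spectra)
  cid <- 0L
  repeat {
    idx <- which(unassigned)
    if (!length(idx)) break
    mu <- m[idx]
    lo <- findInterval(mu * (1 - half), mu) + 1L
    hi <- findInterval(mu * (1 + half), mu)
    support <- hi - lo + 1L            # peak count in window (proxy for spectra)
    if (max(support) < 1L) break
    best <- which(support == max(support))[1L]   # m sorted => smallest m/z wins ties
    center <- mu[best]
    inwin <- idx[abs(m[idx] - center) <= half * center]
    # one peak per spectrum: the one closest to the seed centre
    d <- abs(m[inwin] - center)
    o <- inwin[order(d)]
    sel <- o[!duplicated(pk$sample_id[o])]
    cid <- cid + 1L
    cluster_of[sel] <- cid
    unassigned[sel] <- FALSE
    centers[cid] <- stats::median(m[sel])
    prevalence[cid] <- length(unique(pk$sample_id[sel])) / n_spectra
    # peak support bounds spectrum support from above, so once even the
    # best seed is below the retention threshold nothing more can be kept
    if (min_fraction > 0 && max(support) < min_members) break
  }
  keep <- which(prevalence >= min_fraction)
  ord <- keep[order(centers[keep])]
  relabel <- match(cluster_of, ord)
  members <- pk[!is.na(relabel), , drop = FALSE]
  members$cluster_id <- relabel[!is.na(relabel)]
  list(clusters = data.frame(cluster_id = seq_along(ord),
                             mz_center = centers[ord],
                             prevalence = prevalence[ord]),
       members = members)
}

#' Second pass: cluster completion into a full peak matrix
#'
#' For every spectrum and every retained cluster, the cell value is the
#' height of the spectrum's matched first-pass peak; where no peak was
#' detected, the maximum baseline-corrected intensity inside the
#' cluster's mass window is recorded (the relaxed second pass), and the
#' cell is flagged when that maximum falls below `snr_second` times the
#' local noise.  Cluster windows are centre +/- `cluster_window/2`,
#' trimmed at midpoints so windows never overlap.
#'
#' @param cohort Preprocessed [seldi_cohort()].
#' @param provisional Result of [first_pass_filter()].
#' @param cluster_window Total fractional mass window.
#' @param snr_second Second-pass signal-to-noise threshold.
#' @param noise_window Noise-estimator window in points.
#' @return A complete [peak_matrix()].
#' @export
cluster_and_complete <- function(cohort, provisional, cluster_window = 0.005,
                                 snr_second = 2, noise_window = 151L) {
  cl <- provisional$clusters
  if (!nrow(cl)) stop("no retained clusters to complete")
  half <- cluster_window / 2
  lo <- cl$mz_center * (1 - half)
  hi <- cl$mz_center * (1 + half)
  if (nrow(cl) > 1L) {
    for (i in seq_len(nrow(cl) - 1L)) {
      if (hi[i] > lo[i + 1L]) {
        mid <- (cl$mz_center[i] + cl$mz_center[i + 1L]) / 2
        hi[i] <- mid
        lo[i + 1L] <- mid
      }
    }
  }
  if (any(hi[-length(hi)] > lo[-1L]))
    stop("internal error: overlapping cluster windows after trimming")
  spectra <- cohort$spectra
  nS <- length(spectra)
  nC <- nrow(cl)
  vals <- matrix(0, nS, nC)
  flags <- matrix(FALSE, nS, nC)
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  mem <- provisional$members
  for (i in seq_len(nS)) {
    s <- spectra[[i]]
    st <- detection_state(s, noise_window)
    mi <- mem[mem$sample_id == ids[i], , drop = FALSE]
    have <- rep(FALSE, nC)
    if (nrow(mi)) {
      vals[i, mi$cluster_id] <- mi$height
      have[mi$cluster_id] <- TRUE
    }
    for (j in which(!have)) {
      idx <- which(st$mz >= lo[j] & st$mz <= hi[j])
      if (!length(idx)) { flags[i, j] <- TRUE; next }
      k <- idx[which.max(st$ys[idx] - st$med[idx])]
      vals[i, j] <- max(st$y[k] - st$med[k], 0)
      snr <- if (st$noise[k] > 0) (st$ys[k] - st$med[k]) / st$noise[k]
             else if (st$ys[k] - st$med[k] > 0) Inf else 0
      flags[i, j] <- snr < snr_second
    }
  }
  rownames(vals) <- ids
  clusters <- data.frame(cluster_id = cl$cluster_id, mz_center = cl$mz_center,
                         window_lo = lo, window_hi = hi,
                         prevalence = cl$prevalence)
  peak_matrix(vals, clusters, cohort_labels(cohort), flags)
}

#' Full two-pass peak detection on a preprocessed cohort
#'
#' Convenience driver chaining [detect_peaks()] (signal-to-noise >=
#' `snr_first_pass`), [first_pass_filter()] (minimum peak threshold)
#' and [cluster_and_complete()] (cluster window, second pass).
#'
#' @param cohort Preprocessed [seldi_cohort()].
#' @param config A [pipeline_config()].
#' @return A [peak_matrix()].
#' @export
build_peak_matrix <- function(cohort, config = pipeline_config()) {
  pks <- lapply(cohort$spectra, function(s)
    detect_peaks(s, snr_min = config$snr_first_pass,
                 noise_window = config$noise_window))
  prov <- first_pass_filter(pks, n_spectra = length(cohort$spectra),
                            min_fraction = config$min_peak_threshold,
                            cluster_window = config$cluster_window)
  cluster_and_complete(cohort, prov, cluster_window = config$cluster_window,
                       snr_second = config$snr_second_pass,
                       noise_window = config$noise_window)
}
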