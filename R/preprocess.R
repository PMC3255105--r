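#' Morphological baseline subtraction
#'
#' The baseline is estimated as a rolling minimum over windows of
#' `+/- half_width` points followed by a rolling mean of the same
#' width (an opening-style morphological filter, the standard approach
#' for smooth decaying TOF baselines).  The estimate is clipped to be
#' nonnegative, and the corrected intensity is
#' `max(intensity - baseline, 0)`.
#'
#' @param s A [seldi_spectrum()].
#' @param half_width Window half-width in grid points (> 0).
#' @return The baseline-subtracted spectrum; the baseline itself is
#'   stored in `meta$baseline`.
#' @export
subtract_baseline <- function(s, half_width = 200L) {
  stopifnot(inherits(s, "seldi_spectrum"), half_width > 0)
  if (length(s$mz) < 2L * half_width + 1L)
    stop("spectrum (", length(s$mz), " points) shorter than the baseline ",
         "window (", 2L * half_width + 1L, " points)")
  base <- roll_mean(roll_min(s$intensity, half_width), half_width)
  base <- pmin(pmax(base, 0), s$intensity)
  out <- s
  out$intensity <- pmax(s$intensity - base, 0)
  out$meta$baseline <- base
  out
}

#' Restrict a spectrum to an m/z window
#'
#' The published analysis keeps m/z 2,000-20,000 and discards the
#' low-mass region dominated by energy-absorbing-molecule noise.
#'
#' @param s A [seldi_spectrum()].
#' @param mz_min,mz_max Window bounds in Da (inclusive).
#' @return The windowed spectrum.
#' @export
window_mz <- function(s, mz_min = 2000, mz_max = 20000) {
  stopifnot(inherits(s, "seldi_spectrum"), mz_min < mz_max)
  keep <- s$mz >= mz_min & s$mz <= mz_max
  if (!any(keep))
    stop("no points remain in the m/z window [", mz_min, ", ", mz_max, "]")
  out <- s
  out$mz <- s$mz[keep]
  out$intensity <- s$intensity[keep]
  if (!is.null(out$meta$baseline)) out$meta$baseline <- s$meta$baseline[keep]
  out
}

#' Total-ion-current normalization
#'
#' Scales every spectrum so that its total ion current (the sum of
#' intensities over the common analysis window) equals the cohort mean
#' pre-normalization TIC -- the instrument vendor's convention, which
#' keeps intensities on a scale comparable to the published panel.
#' Spectra must already be baseline-subtracted and windowed to a common
#' range.  Zero-TIC spectra are excluded with a warning rather than
#' silently scaled.
#'
#' @param spectra A list of [seldi_spectrum()] or a [seldi_cohort()].
#' @return Object of the same type; each spectrum's `meta` gains
#'   `tic_raw` and `tic_scale`.
#' @export
normalize_tic <- function(spectra) {
  is_cohort <- inherits(spectra, "seldi_cohort")
  lst <- if (is_cohort) spectra$spectra else spectra
  tic <- vapply(lst, function(s) sum(s$intensity), numeric(1))
  zero <- tic <= 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " zero-TIC spectrum/spectra from ",
            "normalization: ",
            paste(vapply(lst[zero], function(s) s$sample_id, character(1)),
                  collapse = ", "))
    lst <- lst[!zero]
    tic <- tic[!zero]
  }
  if (!length(lst)) stop("no spectra with positive TIC to normalize")
  target <- mean(tic)
  lst <- lapply(seq_along(lst), function(i) {
    s <- lst[[i]]
    s$intensity <- s$intensity * (target / tic[i])
    s$meta$tic_raw <- tic[i]
    s$meta$tic_scale <- target / tic[i]
    s
  })
  if (is_cohort) seldi_cohort(lst, role = spectra$role) else lst
}

#' Preprocess a whole cohort
#'
#' Applies the fixed published order of operations: baseline
#' subtraction, then m/z windowing, then TIC normalization (so
#' low-mass matrix noise never influences the normalization target).
#'
#' @param cohort A [seldi_cohort()].
#' @param config A [pipeline_config()].
#' @return The preprocessed [seldi_cohort()].
#' @export
preprocess_cohort <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "seldi_cohort"))
  lst <- lapply(cohort$spectra, function(s)
    window_mz(subtract_baseline(s, config$baseline_half_width),
              config$mz_min, config$mz_max))
  normalize_tic(seldi_cohort(lst, role = cohort$role))
}
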