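stack_to_matrix <- function(realizations) {
  if (is.array(realizations) && length(dim(realizations)) == 4L) {
    d <- dim(realizations)
    return(list(m = matrix(realizations, nrow = prod(d[1:3])),
                dim = d[1:3], voxel_size = 1))
  }
  if (!is.list(realizations) || length(realizations) < 1L)
    stop("'realizations' must be a list of volume3d or a 4-D array")
  d <- NULL; vs <- 1
  cols <- lapply(realizations, function(v) {
    a <- if (is_volume3d(v)) v$data else v
    if (is_volume3d(v)) vs <<- v$voxel_size
    if (is.null(d)) d <<- dim(a)
    if (!identical(dim(a), d)) stop("realizations differ in shape")
    as.numeric(a)
  })
  list(m = do.call(cbind, cols), dim = d, voxel_size = vs)
}

#' Per-voxel SNR map from repeated realizations
#'
#' Computes, at every voxel, the signal-to-noise ratio
#' `SNR(r) = 20 * log10(mean / sd)` across `N >= 2` independently seeded
#' realizations of the same simulation. Voxels whose mean or standard
#' deviation across the stack is zero (never-visited or constant voxels,
#' whose SNR is undefined or meaningless) are masked invalid rather than
#' mapped to infinities.
#'
#' @param realizations a list of same-shape [volume3d] objects (or a 4-D
#'   array with realizations along the fourth dimension).
#' @param k_label optional photon-count label carried through to the
#'   report.
#' @return An object of class `snr_report`: per-voxel `snr_db` (NA outside
#'   the mask), logical `valid_mask`, `n_realizations`, `k_label`, and
#'   `summary` (the median SNR over valid voxels).
#' @export
snr_map <- function(realizations, k_label = NULL) {
  st <- stack_to_matrix(realizations)
  n <- ncol(st$m)
  if (n < 2L) stop("at least 2 realizations are required")
  mu <- rowMeans(st$m)
  sdv <- sqrt(rowSums((st$m - mu)^2) / (n - 1))
  valid <- mu > 0 & sdv > 0
  snr <- rep(NA_real_, length(mu))
  snr[valid] <- 20 * log10(mu[valid] / sdv[valid])
  structure(list(snr_db = array(snr, st$dim),
                 valid_mask = array(valid, st$dim),
                 mean = array(mu, st$dim),
                 n_realizations = n,
                 k_label = k_label,
                 summary = median(snr[valid])),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> N=%d realizations, %d/%d valid voxels, median SNR %.2f dB\n",
              x$n_realizations, sum(x$valid_mask), length(x$valid_mask),
              x$summary))
  invisible(x)
}

#' SNR improvement map and filter-equivalent photon multiplier
#'
#' Subtracts two SNR maps computed under the same realization protocol
#' (typically before and after denoising) on their jointly valid voxels,
#' forms the "effective region" of voxels improved by more than
#' `threshold_db`, and summarises both the whole-volume and
#' effective-region improvements by their medians (medians, not means, so
#' that unreliable low-photon SNR estimates do not bias the summary). The
#' effective-region median is converted to the filter-equivalent photon
#' multiplier via [photon_multiplier].
#'
#' If no voxel clears the threshold the filter bought nothing and `mf`
#' is reported as 1 (with `median_effective` NA).
#'
#' @param before,after `snr_report` objects on the same grid.
#' @param threshold_db effective-region threshold in dB (default 3).
#' @return An object of class `delta_snr_report` with fields `delta_db`
#'   (map, NA outside the joint mask), `effective_mask`, `median_all`,
#'   `median_effective`, `mf`, `threshold_db` and `n_realizations`.
#' @export
delta_snr <- function(before, after, threshold_db = 3) {
  stopifnot(inherits(before, "snr_report"), inherits(after, "snr_report"))
  if (!identical(dim(before$snr_db), dim(after$snr_db)))
    stop("'before' and 'after' SNR maps are on different grids")
  joint <- before$valid_mask & after$valid_mask
  if (!any(joint)) stop("no jointly valid voxels")
  delta <- array(NA_real_, dim(before$snr_db))
  delta[joint] <- after$snr_db[joint] - before$snr_db[joint]
  eff <- !is.na(delta) & delta > threshold_db
  med_all <- median(delta[joint])
  med_eff <- if (any(eff)) median(delta[eff]) else NA_real_
  structure(list(delta_db = delta, effective_mask = eff,
                 median_all = med_all, median_effective = med_eff,
                 # no voxel clears the threshold: the filter buys nothing
                 mf = if (is.na(med_eff)) 1 else photon_multiplier(med_eff),
                 threshold_db = threshold_db,
                 n_realizations = min(before$n_realizations,
                                      after$n_realizations)),
            class = "delta_snr_report")
}

#' @export
print.delta_snr_report <- function(x, ...) {
  cat(sprintf("<delta_snr_report> median dSNR %.2f dB (all), %.2f dB (effective > %g dB), M_F = %.2f\n",
              x$median_all, x$median_effective, x$threshold_db, x$mf))
  cat(sprintf("  effective region: %d voxels\n", sum(x$effective_mask)))
  invisible(x)
}

#' Filter-equivalent photon-number multiplier
#'
#' Converts an SNR improvement in dB into the factor by which the photon
#' count of the simulation would have to grow to produce the same
#' improvement under shot-noise scaling: `M_F = 10^(dSNR/10)`.
#'
#' @param delta_db SNR improvement in dB.
#' @return The multiplier (1 at 0 dB, 10 at 10 dB).
#' @examples
#' photon_multiplier(5.4)  # ~3.5-fold photons
#' @export
photon_multiplier <- function(delta_db) {
  if (any(!is.finite(delta_db))) stop("'delta_db' must be finite")
  10^(delta_db / 10)
}

#' Expected SNR gain from running more photons
#'
#' Under shot noise, multiplying the photon count by `c` scales the
#' per-voxel standard deviation by `sqrt(c)` relative to the mean, i.e. an
#' expected SNR gain of `10 * log10(c)` dB; a 10-fold photon increase
#' yields about 10 dB. Inverse of [photon_multiplier].
#'
#' @param c photon-count ratio (> 0).
#' @return Expected SNR gain in dB.
#' @export
expected_gain <- function(c) {
  if (any(c <= 0)) stop("'c' must be positive")
  10 * log10(c)
}
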