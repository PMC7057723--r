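#' @useDynLib mcdenoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm rpois runif var
NULL

# Frozen white-noise calibration factors for the adaptive variance estimate
# (see sigma_calibration_factor); keyed "rV_rB".
.sigma_cal_table <- list(
  "1_1" = 1.655850, "1_2" = 1.190785,
  "2_1" = 2.198585, "2_2" = 1.327011,
  "3_1" = 2.612347, "3_2" = 1.434274,
  "4_1" = 2.957974, "4_2" = 1.517040
)

.sigma_cal_cache <- new.env(parent = emptyenv())

gamma_nb <- function(rB) {
  nb <- (2 * rB + 1)^3
  nb / (nb - 1)
}

#' Calibration factor of the adaptive noise-variance estimate
#'
#' The per-voxel noise variance is estimated from the pseudo-residual
#' `R(x) = u(x) - boxmean(u)(x)` as
#' `sigma2(xi) = c(rV, rB) * gamma_B * min over xj in Vi of boxmean(R^2)(xj)`,
#' where `gamma_B = NB/(NB-1)` removes the small-sample bias of a single
#' squared residual and the search-volume minimum guards the estimate
#' against inflation by structure (edges, gradients). The minimum of many
#' correlated local averages systematically undershoots the true variance,
#' so a multiplicative factor `c(rV, rB)` is calibrated once, by simulation
#' on i.i.d. standard Gaussian volumes, such that the estimator is unbiased
#' for spatially white noise. Factors for common radii are precomputed and
#' frozen; other combinations are simulated on demand (with a fixed internal
#' seed, so the filter stays deterministic) and cached for the session.
#'
#' @param rV search radius in voxels.
#' @param rB box-filter radius in voxels.
#' @return The scalar calibration factor `c(rV, rB)`.
#' @export
sigma_calibration_factor <- function(rV, rB) {
  key <- sprintf("%d_%d", as.integer(rV), as.integer(rB))
  if (!is.null(.sigma_cal_table[[key]])) return(.sigma_cal_table[[key]])
  if (!is.null(.sigma_cal_cache[[key]])) return(.sigma_cal_cache[[key]])
  val <- simulate_sigma_calibration(rV, rB)
  assign(key, val, envir = .sigma_cal_cache)
  val
}

# Mean of the uncalibrated estimator on white noise, inverted. Fixed seed:
# the factor is a property of the estimator's geometry, not of the data.
simulate_sigma_calibration <- function(rV, rB, n = 24L, nrep = 12L,
                                       seed = 603001L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  acc <- 0
  for (i in seq_len(nrep)) {
    u <- array(rnorm(n^3), c(n, n, n))
    pre <- cpp_anlm_precompute(u, dim(u), as.integer(rV), 1L,
                               as.integer(rB), gamma_nb(rB), 0)
    acc <- acc + mean(pre$sigma2)
  }
  1 / (acc / nrep)
}

#' Box-filter a volume
#'
#' Replaces each voxel by the arithmetic mean of its cubic
#' `(2*rB+1)^3`-voxel neighbourhood. At the volume boundary the
#' neighbourhood is clipped and the divisor reduced to the number of voxels
#' actually present.
#'
#' @param u a [volume3d].
#' @param rB box radius in voxels (>= 1).
#' @return A [volume3d] of the same shape.
#' @export
box_filter <- function(u, rB = 1L) {
  assert_volume3d(u)
  rB <- as.integer(rB)
  if (rB < 1L) stop("'rB' must be >= 1")
  out <- cpp_box_mean_clipped(u$data, dim(u$data), rB)
  volume3d(array(out, dim(u$data)), u$voxel_size, u$scale)
}

#' Pseudo-residual map
#'
#' The residual `R(x) = u(x) - boxmean(u)(x)`: what is left after removing
#' the locally smooth component, i.e. (mostly) the noise.
#'
#' @inheritParams box_filter
#' @return A [volume3d] of residuals (may be negative; scale metadata is
#'   carried through unchanged).
#' @export
residual_map <- function(u, rB = 1L) {
  assert_volume3d(u)
  b <- box_filter(u, rB)
  r <- u$data - b$data
  structure(list(data = r, voxel_size = u$voxel_size, scale = u$scale),
            class = "volume3d")
}

#' Precompute the filter's per-voxel statistics
#'
#' Runs the preprocessing stage of the ANLM filter on a mirror-padded copy
#' of the volume: box means and box variances (used by patch preselection),
#' the pseudo-residual, and the spatially adaptive noise variance
#' `sigma2(xi)` (see [sigma_calibration_factor] for its exact definition).
#'
#' @param u a [volume3d].
#' @param p a [filter_params].
#' @return A list of class `anlm_precomputed` with [volume3d] fields
#'   `box_mean`, `box_var`, `residual` and `sigma2`.
#' @export
anlm_precompute <- function(u, p = filter_params()) {
  assert_volume3d(u)
  stopifnot(inherits(p, "filter_params"))
  g <- gamma_nb(p$rB) * sigma_calibration_factor(p$rV, p$rB)
  pre <- cpp_anlm_precompute(u$data, dim(u$data), p$rV, p$rP, p$rB,
                             g, p$min_sigma)
  d <- dim(u$data)
  out <- lapply(pre, function(x)
    structure(list(data = array(x, d), voxel_size = u$voxel_size,
                   scale = u$scale), class = "volume3d"))
  structure(out, class = c("anlm_precomputed", "list"))
}

#' Adaptive noise-variance map
#'
#' The per-voxel noise variance `sigma2(xi)` driving the filter bandwidth
#' `h(xi)^2 = 2*beta*sigma2(xi)`; clamped below at `min_sigma^2`.
#'
#' @inheritParams anlm_precompute
#' @return A [volume3d] of variances.
#' @export
adaptive_sigma2 <- function(u, p = filter_params()) {
  anlm_precompute(u, p)$sigma2
}

#' Normalised squared patch distance
#'
#' The squared L2 distance between the cubic radius-`rP` patches centred at
#' `xi` and `xj`, divided by the patch voxel count `(2*rP+1)^3`. Both
#' patches must lie fully inside the (padded) array.
#'
#' @param u_pad a 3-D numeric array (typically a mirror-padded volume).
#' @param xi,xj 1-based integer index triples of the patch centres.
#' @param rP patch radius in voxels.
#' @return Non-negative scalar.
#' @export
patch_distance2 <- function(u_pad, xi, xj, rP) {
  if (is_volume3d(u_pad)) u_pad <- u_pad$data
  rP <- as.integer(rP)
  sl <- function(c) lapply(seq_len(3), function(a) (c[a] - rP):(c[a] + rP))
  si <- sl(as.integer(xi)); sj <- sl(as.integer(xj))
  pi_ <- u_pad[si[[1]], si[[2]], si[[3]], drop = FALSE]
  pj_ <- u_pad[sj[[1]], sj[[2]], sj[[3]], drop = FALSE]
  sum((pi_ - pj_)^2) / (2 * rP + 1)^3
}

ratio_within <- function(a, b, lo, hi, tiny) {
  if (b <= tiny) return(a <= tiny)
  if (a <= tiny) return(FALSE)
  r <- a / b
  r >= lo && r <= hi
}

#' Patch preselection test
#'
#' Decides whether candidate voxel `xj` is kept for the weighted average at
#' `xi`: the box-mean ratio must lie in
#' `[presel_mean_ratio, 1/presel_mean_ratio]` and the box-variance ratio in
#' `[presel_var_low, presel_var_high]`. Near-zero statistics (below a
#' scale-invariant tolerance of `1e-12` times the volume maximum) on one
#' side only fail the test; on both sides they pass it.
#'
#' @param pre an [anlm_precompute] result.
#' @param xi,xj 1-based integer index triples into the volume.
#' @param p a [filter_params].
#' @return `TRUE` if the candidate is kept.
#' @export
preselect <- function(pre, xi, xj, p = filter_params()) {
  bm <- pre$box_mean$data; bv <- pre$box_var$data
  tiny_m <- 1e-12 * max(bm); tiny_v <- 1e-12 * max(bv)
  xi <- as.integer(xi); xj <- as.integer(xj)
  mi <- bm[xi[1], xi[2], xi[3]]; mj <- bm[xj[1], xj[2], xj[3]]
  vi <- bv[xi[1], xi[2], xi[3]]; vj <- bv[xj[1], xj[2], xj[3]]
  ratio_within(mi, mj, p$presel_mean_ratio, 1 / p$presel_mean_ratio, tiny_m) &&
    ratio_within(vi, vj, p$presel_var_low, p$presel_var_high, tiny_v)
}

#' Rician bias correction
#'
#' Removes the noise-floor bias of magnitude (Rician) data from a filtered
#' second moment: `sqrt(max(m2 - 2*sigma2, 0))` per voxel.
#'
#' @param m2 [volume3d] (or array) of weighted second moments.
#' @param sigma2 [volume3d] (or array) of per-voxel noise variances.
#' @return A [volume3d] (or array, matching `m2`) of corrected magnitudes.
#' @export
rician_correct <- function(m2, sigma2) {
  s2 <- if (is_volume3d(sigma2)) sigma2$data else sigma2
  if (is_volume3d(m2)) {
    out <- sqrt(pmax(m2$data - 2 * s2, 0))
    volume3d(array(out, dim(m2$data)), m2$voxel_size, m2$scale)
  } else {
    sqrt(pmax(m2 - 2 * s2, 0))
  }
}

filter_pass_impl <- function(u, p, block_dims) {
  assert_volume3d(u)
  stopifnot(inherits(p, "filter_params"))
  if (u$scale != "linear")
    stop("filter_pass operates on linear-scale fluence; convert log10 data back to linear first")
  g <- gamma_nb(p$rB) * sigma_calibration_factor(p$rV, p$rB)
  rician <- p$noise_model == "rician"
  out <- cpp_filter_pass(u$data, dim(u$data), p$rV, p$rP, p$rB,
                         p$beta, p$presel_mean_ratio,
                         p$presel_var_low, p$presel_var_high,
                         p$min_sigma, g, rician,
                         as.integer(block_dims))
  out <- array(out, dim(u$data))
  if (rician) {
    s2 <- cpp_anlm_precompute(u$data, dim(u$data), p$rV, p$rP, p$rB,
                              g, p$min_sigma)$sigma2
    out <- sqrt(pmax(out - 2 * array(s2, dim(u$data)), 0))
  }
  volume3d(out, u$voxel_size, "linear")
}

#' One adaptive nonlocal means filter pass
#'
#' Filters a linear-scale fluence volume by the spatially adaptive
#' nonlocal means update: each voxel becomes the normalised weighted
#' average of the candidates in its search volume, with weights
#' `exp(-d2(xi,xj) / h(xi)^2)`, `h(xi)^2 = 2*beta*sigma2(xi)`, patch
#' preselection on box-mean and box-variance ratios, and the centre voxel
#' carrying the maximum accepted weight. In `"rician"` mode squared
#' magnitudes are averaged and the Rician noise floor subtracted
#' afterwards. Where `sigma2(xi) = 0` (e.g. locally constant data) the
#' voxel is returned unchanged. The volume is mirror-padded internally so
#' that every search volume and patch is complete.
#'
#' @param u a linear-scale [volume3d].
#' @param p a [filter_params].
#' @return The filtered [volume3d].
#' @seealso [anlm_denoise()] for the full two-pass, sub-band-mixed filter.
#' @export
filter_pass <- function(u, p = filter_params()) {
  filter_pass_impl(u, p, c(0L, 0L, 0L))
}

#' Tiled filter pass
#'
#' Runs [filter_pass] block by block: the volume is partitioned into blocks
#' of `t$block_dims` voxels and each block is processed using only the
#' block plus its apron margin of `rV + rP` voxels per side. Preprocessing
#' statistics are computed once globally (as in the two-stage workflow the
#' filter is designed around), so the tiled result is bit-identical to the
#' untiled one.
#'
#' @inheritParams filter_pass
#' @param t a [tile_spec]; its apron must equal `p$rV + p$rP`.
#' @return The filtered [volume3d], identical to `filter_pass(u, p)`.
#' @export
tiled_filter <- function(u, p, t) {
  if (!inherits(t, "tile_spec")) stop("'t' must be a tile_spec")
  if (t$apron != p$rV + p$rP)
    stop(sprintf("tile apron (%d) must equal rV + rP (%d)",
                 t$apron, p$rV + p$rP))
  filter_pass_impl(u, p, t$block_dims)
}

#' Denoise a fluence volume (full ANLM with sub-band mixing)
#'
#' The complete denoiser: two independent filter passes with small
#' (`rP = 1`) and large (`rP = 2`) patches, combined by 3-D Haar wavelet
#' sub-band mixing — the approximation band from the large-patch pass, the
#' detail bands from the small-patch pass. Deterministic: identical input
#' yields identical output.
#'
#' @param u a linear-scale [volume3d].
#' @param params_small parameters of the small-patch pass.
#' @param params_large parameters of the large-patch pass; must differ from
#'   `params_small` only in `rP`.
#' @return The denoised [volume3d].
#' @examples
#' v <- volume3d(array(5, c(12, 12, 12)))
#' d <- anlm_denoise(v)
#' max(abs(d$data - 5))  # constant volumes are fixed points
#' @export
anlm_denoise <- function(u,
                         params_small = filter_params(rP = 1L),
                         params_large = filter_params(rP = 2L)) {
  a <- params_small; b <- params_large
  a$rP <- b$rP <- NULL
  if (!identical(a, b))
    stop("'params_small' and 'params_large' must differ only in rP")
  v_small <- filter_pass(u, params_small)
  v_large <- filter_pass(u, params_large)
  out <- subband_mix(v_small, v_large)
  # sub-band mixing can leave tiny negative excursions; fluence is not
  out$data <- pmax(out$data, 0)
  out
}
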