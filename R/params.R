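#' ANLM filter parameters
#'
#' Collects every tunable of the adaptive nonlocal means filter. The three
#' radii define nested cubic neighbourhoods around each voxel: the search
#' volume `Vi` of radius `rV` holds `(2*rV+1)^3` candidate voxels, the
#' local/nonlocal patches `Pi`/`Pj` of radius `rP` hold `(2*rP+1)^3` voxels
#' compared by L2 distance, and the box-filter region of radius `rB` (with
#' `(2*rB+1)^3` voxels) feeds the pseudo-residual noise estimate and the
#' preselection statistics.
#'
#' @param rV search radius in voxels. Default 3, giving a 343-voxel search
#'   volume; larger radii were found to add little.
#' @param rP patch radius in voxels; the two sub-band-mixed passes use 1
#'   and 2.
#' @param rB box-filter radius in voxels for the noise pre-estimate.
#' @param noise_model `"gaussian"` (MC fluence shot noise in its Gaussian
#'   regime) or `"rician"` (magnitude MRI data; applies a second-moment
#'   bias correction).
#' @param beta positive bandwidth scale: the filter bandwidth is
#'   `h(xi)^2 = 2 * beta * sigma2(xi)` against the per-voxel-normalised
#'   squared patch distance.
#' @param presel_mean_ratio candidates are kept only when the box-mean
#'   ratio `mu(xi)/mu(xj)` lies in `[presel_mean_ratio, 1/presel_mean_ratio]`.
#' @param presel_var_low,presel_var_high bounds on the box-variance ratio
#'   `var(Bxi)/var(Bxj)` for preselection.
#' @param min_sigma non-negative floor on the adaptive noise standard
#'   deviation `sigma(xi)`.
#' @return An object of class `filter_params`.
#' @examples
#' p <- filter_params(rP = 1)
#' search_volume_voxels(p)  # 343 at the default rV = 3
#' @export
filter_params <- function(rV = 3L, rP = 1L, rB = 1L,
                          noise_model = c("gaussian", "rician"),
                          beta = 1.0,
                          presel_mean_ratio = 0.95,
                          presel_var_low = 0.5,
                          presel_var_high = 2.0,
                          min_sigma = 0.0) {
  noise_model <- match.arg(noise_model)
  rV <- as.integer(rV); rP <- as.integer(rP); rB <- as.integer(rB)
  if (rV < 1L || rP < 0L || rB < 1L)
    stop("radii must satisfy rV >= 1, rP >= 0, rB >= 1")
  if (rP >= rV)
    stop("the patch radius rP must be strictly smaller than the search radius rV")
  if (!is.numeric(beta) || beta <= 0) stop("'beta' must be positive")
  if (presel_mean_ratio <= 0 || presel_mean_ratio > 1)
    stop("'presel_mean_ratio' must be in (0, 1]")
  if (presel_var_low <= 0 || presel_var_low > 1 || presel_var_high < 1)
    stop("variance-ratio bounds must satisfy 0 < low <= 1 <= high")
  if (min_sigma < 0) stop("'min_sigma' must be non-negative")
  structure(list(rV = rV, rP = rP, rB = rB, noise_model = noise_model,
                 beta = beta, presel_mean_ratio = presel_mean_ratio,
                 presel_var_low = presel_var_low,
                 presel_var_high = presel_var_high,
                 min_sigma = min_sigma),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "<filter_params> rV=%d rP=%d rB=%d, %s noise, beta=%.3g\n",
    x$rV, x$rP, x$rB, x$noise_model, x$beta))
  cat(sprintf("  preselection: mean ratio >= %.3g, var ratio in [%.3g, %.3g]; min_sigma=%.3g\n",
              x$presel_mean_ratio, x$presel_var_low, x$presel_var_high,
              x$min_sigma))
  invisible(x)
}

#' Neighbourhood voxel counts
#'
#' Convenience accessors for the sizes of the cubic neighbourhoods implied
#' by a parameter set: `(2r+1)^3` voxels for a radius-`r` cube.
#'
#' @param p a [filter_params].
#' @return Integer voxel count.
#' @export
search_volume_voxels <- function(p) as.integer((2L * p$rV + 1L)^3)
#' @rdname search_volume_voxels
#' @export
patch_voxels <- function(p) as.integer((2L * p$rP + 1L)^3)
#' @rdname search_volume_voxels
#' @export
box_voxels <- function(p) as.integer((2L * p$rB + 1L)^3)

#' Tile specification for blocked execution
#'
#' Describes how a volume is partitioned into blocks for tiled filtering.
#' Each block must be processed together with an "apron" margin of
#' `rV + rP` voxels on every side so that every search volume and every
#' patch referenced by a block voxel is available; the loaded subvolume for
#' an interior block therefore has
#' `(Tx + 2*(rV+rP)) * (Ty + 2*(rV+rP)) * (Tz + 2*(rV+rP))` voxels.
#'
#' @param block_dims three positive integers `(Tx, Ty, Tz)`.
#' @param rV,rP the filter radii the tiling must accommodate.
#' @param apron margin width in voxels; must equal `rV + rP` (the default).
#' @return An object of class `tile_spec` with fields `block_dims` and
#'   `apron`.
#' @examples
#' t <- tile_spec(c(16, 16, 16), rV = 3, rP = 2)
#' tile_load_voxels(t)  # 26^3 = 17576
#' @export
tile_spec <- function(block_dims, rV = 3L, rP = 2L, apron = rV + rP) {
  block_dims <- as.integer(block_dims)
  if (length(block_dims) != 3L || any(is.na(block_dims)) ||
      any(block_dims < 1L))
    stop("'block_dims' must be three positive integers")
  apron <- as.integer(apron)
  if (apron != as.integer(rV) + as.integer(rP))
    stop(sprintf("apron must equal rV + rP = %d, got %d",
                 as.integer(rV) + as.integer(rP), apron))
  structure(list(block_dims = block_dims, apron = apron),
            class = "tile_spec")
}

#' Voxels loaded per tile
#'
#' The number of voxels in the subvolume that must be loaded to filter one
#' interior block: the block itself plus the apron margin on both sides of
#' each axis (before any clipping at the volume boundary).
#'
#' @param t a [tile_spec].
#' @return Numeric voxel count.
#' @export
tile_load_voxels <- function(t) {
  if (!inherits(t, "tile_spec")) stop("'t' must be a tile_spec")
  prod(t$block_dims + 2 * t$apron)
}
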