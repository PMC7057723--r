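#' Voxelised optical medium
#'
#' Per-voxel optical properties for the photon-transport simulator:
#' absorption `mua` (1/mm), scattering `mus` (1/mm), scattering anisotropy
#' `g` (mean cosine, dimensionless) and refractive index `n`. Scalars are
#' expanded to the full grid.
#'
#' @param mua,mus,g,n scalar values or 3-D arrays of grid shape.
#' @param grid three positive integers (or one, recycled) giving the voxel
#'   grid extents.
#' @param voxel_size isotropic voxel edge length in mm.
#' @return An object of class `mc_medium`.
#' @export
medium <- function(mua = 0.02, mus = 10, g = 0.9, n = 1.37,
                   grid = c(50L, 50L, 50L), voxel_size = 1) {
  grid <- rep_len(as.integer(grid), 3L)
  if (any(grid < 1L)) stop("grid extents must be >= 1")
  expand <- function(x, what) {
    if (length(x) == 1L) x <- array(x, grid)
    if (!identical(dim(x), as.integer(grid)))
      stop(sprintf("'%s' must be scalar or an array of grid shape", what))
    x
  }
  mua <- expand(mua, "mua"); mus <- expand(mus, "mus")
  g <- expand(g, "g"); n <- expand(n, "n")
  if (any(mua < 0) || any(mus < 0)) stop("mua and mus must be non-negative")
  if (any(g < -1) || any(g > 1)) stop("g must lie in [-1, 1]")
  if (any(n < 1)) stop("refractive index must be >= 1")
  structure(list(mua = mua, mus = mus, g = g, n = n,
                 grid = grid, voxel_size = as.numeric(voxel_size)),
            class = "mc_medium")
}

#' @export
print.mc_medium <- function(x, ...) {
  cat(sprintf("<mc_medium> %d x %d x %d voxels, %.3g mm\n",
              x$grid[1], x$grid[2], x$grid[3], x$voxel_size))
  cat(sprintf("  mua [%.3g, %.3g], mus [%.3g, %.3g], g [%.3g, %.3g], n [%.3g, %.3g]\n",
              min(x$mua), max(x$mua), min(x$mus), max(x$mus),
              min(x$g), max(x$g), min(x$n), max(x$n)))
  invisible(x)
}

#' Standard benchmark media
#'
#' The three benchmark domains used to exercise the filter, scaled
#' proportionally to any grid size. At full scale (grid 100, 1 mm voxels):
#' B1 is homogeneous with `mua = 0.02/mm`, `mus = 10/mm`, `g = 0.9`,
#' `n = 1.37`; B2 adds a 40 mm cubic absorber centred at (50, 50, 30) mm
#' with five-fold absorption contrast (`mua = 0.1/mm`); B3 instead gives
#' the cube a five-fold refractive-index contrast (`n = 6.85`), probing
#' edge preservation across a fluence discontinuity.
#'
#' @param name `"B1"`, `"B2"` or `"B3"`.
#' @param grid grid extent per axis (cubic; default 100).
#' @param voxel_size voxel edge length in mm.
#' @return An [medium] object.
#' @examples
#' m <- build_benchmark("B2", grid = 100)
#' m$mua[50, 50, 30]  # inside the absorber: 0.1
#' @export
build_benchmark <- function(name = c("B1", "B2", "B3"), grid = 100L,
                            voxel_size = 1) {
  name <- match.arg(name)
  grid <- rep_len(as.integer(grid), 3L)
  m <- medium(0.02, 10, 0.9, 1.37, grid = grid, voxel_size = voxel_size)
  if (name == "B1") return(m)
  # inclusion spans fractions [0.3, 0.7] x [0.3, 0.7] x [0.1, 0.5] of the
  # domain (the 40 mm cube centred at (50, 50, 30) mm at full scale)
  centres <- lapply(grid, function(n) ((seq_len(n)) - 0.5) / n)
  inx <- centres[[1]] > 0.3 & centres[[1]] < 0.7
  iny <- centres[[2]] > 0.3 & centres[[2]] < 0.7
  inz <- centres[[3]] > 0.1 & centres[[3]] < 0.5
  mask <- outer(outer(inx, iny, "&"), inz, "&")
  if (name == "B2") m$mua[mask] <- 0.1 else m$n[mask] <- 6.85
  m
}

#' Simulation configuration
#'
#' Photon-packet count, source definition, RNG seed and Russian-roulette
#' survival parameters for [mc_fluence].
#'
#' @param nphoton number of photon packets (>= 1).
#' @param source_pos source position in mm.
#' @param source_dir unit direction vector (normalised internally; must be
#'   within 1e-9 of unit length afterwards).
#' @param seed RNG seed (non-negative integer).
#' @param launch `"pencil"` (collimated beam along `source_dir`) or
#'   `"isotropic"` (point source).
#' @param roulette_threshold packet weight below which Russian roulette is
#'   played.
#' @param roulette_chance survival probability in roulette; survivors are
#'   reweighted by its inverse.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(nphoton = 1e5, source_pos = c(25, 25, 0),
                       source_dir = c(0, 0, 1), seed = 1L,
                       launch = c("pencil", "isotropic"),
                       roulette_threshold = 1e-4, roulette_chance = 0.1) {
  launch <- match.arg(launch)
  if (nphoton < 1) stop("'nphoton' must be >= 1")
  nrm <- sqrt(sum(source_dir^2))
  if (nrm == 0) stop("'source_dir' must be a nonzero vector")
  source_dir <- source_dir / nrm
  if (abs(sqrt(sum(source_dir^2)) - 1) > 1e-9)
    stop("'source_dir' could not be normalised to unit length")
  if (roulette_chance <= 0 || roulette_chance > 1)
    stop("'roulette_chance' must be in (0, 1]")
  structure(list(nphoton = nphoton, source_pos = as.numeric(source_pos),
                 source_dir = as.numeric(source_dir),
                 seed = as.numeric(seed), launch = launch,
                 roulette_threshold = roulette_threshold,
                 roulette_chance = roulette_chance),
            class = "sim_config")
}

#' Monte Carlo fluence simulation
#'
#' Runs the minimal voxel photon-packet Monte Carlo: exponentially sampled
#' scattering lengths, Henyey-Greenstein scattering, continuous absorption
#' weighting, Fresnel reflection/refraction at internal refractive-index
#' boundaries, a matched (non-reflecting) outer boundary, and Russian
#' roulette. Fluence is tallied with the path-length estimator and
#' normalised per launched packet (units 1/mm^2), which stays well defined
#' as `mua` approaches zero. Fully reproducible for a fixed seed.
#'
#' The returned volume carries an `energy` attribute with the weight
#' bookkeeping (`launched`, `absorbed`, `escaped`, `killed` in roulette,
#' `boosted` by roulette survival); `launched + boosted =
#' absorbed + escaped + killed` holds to double precision.
#'
#' @param m an [medium].
#' @param cfg a [sim_config]; the source must lie inside or on the domain
#'   boundary.
#' @return A [volume3d] of fluence per launched packet, with attribute
#'   `energy`.
#' @export
mc_fluence <- function(m, cfg) {
  stopifnot(inherits(m, "mc_medium"), inherits(cfg, "sim_config"))
  ext <- m$grid * m$voxel_size
  if (any(cfg$source_pos < 0) || any(cfg$source_pos > ext))
    stop("source position must lie inside or on the domain boundary")
  res <- cpp_mc_fluence(m$mua, m$mus, m$g, m$n, m$grid, m$voxel_size,
                        cfg$nphoton, cfg$source_pos, cfg$source_dir,
                        as.integer(cfg$launch == "isotropic"),
                        cfg$roulette_threshold, cfg$roulette_chance,
                        cfg$seed)
  v <- volume3d(array(res$phi, m$grid), m$voxel_size, "linear")
  attr(v, "energy") <- res[c("launched", "absorbed", "escaped",
                             "killed", "boosted")]
  v
}

#' Analytic diffusion fluence of a point source
#'
#' The infinite-medium diffusion-approximation Green's function for a
#' homogeneous medium,
#' `phi(r) = exp(-mueff * r) / (4 * pi * D * r)`, with diffusion
#' coefficient `D = 1/(3*(mua + mus*(1-g)))` and effective attenuation
#' `mueff = sqrt(3*mua*(mua + mus*(1-g)))`. Valid in the
#' scattering-dominated regime `mus*(1-g) >> mua`. The value at the source
#' voxel is capped at the value one voxel away. Used as a smooth noise-free
#' reference field; it is not itself a transport solution near the source
#' or boundaries.
#'
#' @param m a homogeneous [medium] (uniform optical properties).
#' @param source_pos source position in mm.
#' @param grid optional grid extents (defaults to the medium's).
#' @return A [volume3d] of the analytic fluence.
#' @export
diffusion_fluence <- function(m, source_pos, grid = m$grid) {
  stopifnot(inherits(m, "mc_medium"))
  props <- c(m$mua[1], m$mus[1], m$g[1])
  if (any(m$mua != props[1]) || any(m$mus != props[2]) ||
      any(m$g != props[3]))
    stop("diffusion_fluence requires a homogeneous medium")
  mua <- props[1]; musp <- props[2] * (1 - props[3])
  if (musp <= 0) stop("reduced scattering must be positive")
  D <- 1 / (3 * (mua + musp))
  mueff <- sqrt(3 * mua * (mua + musp))
  vs <- m$voxel_size
  grid <- rep_len(as.integer(grid), 3L)
  cx <- (seq_len(grid[1]) - 0.5) * vs
  cy <- (seq_len(grid[2]) - 0.5) * vs
  cz <- (seq_len(grid[3]) - 0.5) * vs
  r2 <- outer(outer((cx - source_pos[1])^2, (cy - source_pos[2])^2, "+"),
              (cz - source_pos[3])^2, "+")
  r <- sqrt(r2)
  cap <- exp(-mueff * vs) / (4 * pi * D * vs)
  phi <- ifelse(r < vs, cap, exp(-mueff * r) / (4 * pi * D * r))
  volume3d(phi, vs, "linear")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add photon shot noise to a noise-free fluence field
#'
#' Emulates the counting statistics of a Monte Carlo simulation: the
#' noise-free field is converted to expected per-voxel photon visit counts
#' `lambda = phi * k_total / sum(phi)`, a Poisson draw is taken per voxel
#' (the noise standard deviation therefore equals the square root of the
#' local count), and the counts are rescaled back to fluence units. For
#' `lambda > 50` the Gaussian approximation `N(lambda, sqrt(lambda))`
#' (clamped at zero) is used.
#'
#' @param phi a non-negative linear-scale [volume3d].
#' @param k_total effective total photon budget distributed over the field.
#' @param seed RNG seed; the draw is reproducible and leaves the caller's
#'   RNG state untouched.
#' @return A noisy [volume3d] of the same shape and scale.
#' @export
add_shot_noise <- function(phi, k_total, seed = NULL) {
  assert_volume3d(phi)
  if (phi$scale != "linear") stop("'phi' must be linear-scale")
  if (any(phi$data < 0)) stop("'phi' must be non-negative")
  if (k_total <= 0) stop("'k_total' must be positive")
  s <- sum(phi$data)
  if (s == 0) return(phi)
  lam <- as.numeric(phi$data) * (k_total / s)
  draw <- function() {
    out <- numeric(length(lam))
    hi <- lam > 50
    if (any(hi)) out[hi] <- pmax(rnorm(sum(hi), lam[hi], sqrt(lam[hi])), 0)
    if (any(!hi)) out[!hi] <- rpois(sum(!hi), lam[!hi])
    out
  }
  counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  volume3d(array(counts * (s / k_total), dim(phi$data)),
           phi$voxel_size, "linear")
}

#' Separable Gaussian comparison filter
#'
#' A plain 3-D Gaussian smoothing filter (truncated separable kernel,
#' renormalised at the boundary), included as the non-adaptive baseline
#' that the ANLM filter is compared against on edge phantoms.
#'
#' @param u a [volume3d].
#' @param sigma_mm Gaussian standard deviation in mm.
#' @param radius kernel half-width in voxels.
#' @return The smoothed [volume3d].
#' @export
gaussian_smooth3d <- function(u, sigma_mm = 0.67, radius = 2L) {
  assert_volume3d(u)
  vs <- u$voxel_size[1]
  k <- exp(-((-radius:radius) * vs)^2 / (2 * sigma_mm^2))
  k <- k / sum(k)
  arr <- u$data
  for (axis in 1:3) {
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    n <- dim(a)[1]
    m <- matrix(a, nrow = n)
    out <- matrix(0, nrow = n, ncol = ncol(m))
    wsum <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - radius - 1L
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      out[keep, ] <- out[keep, ] + k[j] * m[src[keep], , drop = FALSE]
      wsum[keep] <- wsum[keep] + k[j]
    }
    out <- out / wsum
    arr <- aperm(array(out, dim(a)), order(perm))
  }
  volume3d(arr, u$voxel_size, u$scale)
}
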