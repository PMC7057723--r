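# Single-level orthonormal 3-D Haar transform and sub-band mixing.
#
# Odd extents are handled by replicating the last slice before pairing;
# the inverse transform reconstructs the padded signal exactly and then
# drops the padding, so the round trip is exact to float precision.

haar_axis_fwd <- function(arr, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_len(3), axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  if (n %% 2L == 1L) {
    a <- a[c(seq_len(n), n), , , drop = FALSE] # replicate the last slice
    n <- n + 1L
  }
  m <- matrix(a, nrow = n)
  e <- m[seq(1L, n, by = 2L), , drop = FALSE]
  o <- m[seq(2L, n, by = 2L), , drop = FALSE]
  out <- rbind((e + o) / sqrt(2), (e - o) / sqrt(2))
  out <- array(out, dim = c(n, dim(a)[2:3]))
  aperm(out, order(perm))
}

haar_axis_inv <- function(arr, axis, orig_len) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_len(3), axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  h <- n %/% 2L
  m <- matrix(a, nrow = n)
  lo <- m[seq_len(h), , drop = FALSE]
  hi <- m[h + seq_len(h), , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  out[seq(1L, n, by = 2L), ] <- (lo + hi) / sqrt(2)
  out[seq(2L, n, by = 2L), ] <- (lo - hi) / sqrt(2)
  out <- array(out, dim = dim(a))
  if (orig_len < n)
    out <- out[seq_len(orig_len), , , drop = FALSE]
  aperm(out, order(perm))
}

subband_names <- function() {
  bands <- expand.grid(x = c("L", "H"), y = c("L", "H"), z = c("L", "H"),
                       stringsAsFactors = FALSE)
  paste0(bands$x, bands$y, bands$z)
}

#' Single-level 3-D Haar decomposition
#'
#' Decomposes a volume into its eight orthonormal Haar sub-bands (`LLL` ...
#' `HHH`; letter order is x, y, z, `L` = approximation, `H` = detail). The
#' transform is orthonormal, so energy is preserved and the inverse
#' ([idwt3]) reconstructs the input exactly to float precision.
#'
#' @param v a [volume3d] or 3-D array.
#' @return An object of class `subbands3d`: a list of the eight coefficient
#'   arrays plus `orig_dim`, `voxel_size` and `scale` metadata.
#' @export
dwt3 <- function(v) {
  meta <- list(voxel_size = 1, scale = "linear")
  if (is_volume3d(v)) {
    meta <- list(voxel_size = v$voxel_size, scale = v$scale)
    v <- v$data
  }
  if (!is.array(v) || length(dim(v)) != 3L) stop("'v' must be a 3-D array")
  orig <- dim(v)
  w <- haar_axis_fwd(haar_axis_fwd(haar_axis_fwd(v, 1L), 2L), 3L)
  h <- dim(w) %/% 2L
  idx <- list(L = lapply(h, seq_len),
              H = lapply(seq_len(3), function(a) h[a] + seq_len(h[a])))
  bands <- list()
  for (nm in subband_names()) {
    parts <- strsplit(nm, "")[[1]]
    bands[[nm]] <- w[idx[[parts[1]]][[1]], idx[[parts[2]]][[2]],
                     idx[[parts[3]]][[3]], drop = FALSE]
  }
  structure(c(bands, list(orig_dim = orig, voxel_size = meta$voxel_size,
                          scale = meta$scale)),
            class = "subbands3d")
}

#' Inverse single-level 3-D Haar transform
#'
#' @param s a `subbands3d` object from [dwt3].
#' @return The reconstructed [volume3d].
#' @rdname dwt3
#' @export
idwt3 <- function(s) {
  if (!inherits(s, "subbands3d")) stop("'s' must be a subbands3d object")
  if (is.null(s$orig_dim)) stop("sub-band set lacks original shape metadata")
  h <- dim(s$LLL)
  w <- array(0, dim = 2L * h)
  idx <- list(L = lapply(h, seq_len),
              H = lapply(seq_len(3), function(a) h[a] + seq_len(h[a])))
  for (nm in subband_names()) {
    parts <- strsplit(nm, "")[[1]]
    w[idx[[parts[1]]][[1]], idx[[parts[2]]][[2]],
      idx[[parts[3]]][[3]]] <- s[[nm]]
  }
  ext <- ifelse(s$orig_dim %% 2L == 1L, s$orig_dim + 1L, s$orig_dim)
  out <- haar_axis_inv(w, 3L, ext[3])
  out <- haar_axis_inv(out, 2L, ext[2])
  out <- haar_axis_inv(out, 1L, ext[1])
  out <- out[seq_len(s$orig_dim[1]), seq_len(s$orig_dim[2]),
             seq_len(s$orig_dim[3]), drop = FALSE]
  structure(list(data = out, voxel_size = s$voxel_size, scale = s$scale),
            class = "volume3d")
}

#' Wavelet sub-band mixing of two filtered volumes
#'
#' Combines the outputs of the small-patch and large-patch filter passes:
#' both volumes are Haar-decomposed, the approximation band (`LLL`) is
#' taken from `v_large` (the smoother large-patch result) and all seven
#' detail bands from `v_small` (which preserves fine structure better),
#' and the mix is inverse-transformed. Identical inputs are returned
#' unchanged (to float precision).
#'
#' @param v_small [volume3d] filtered with the small patch radius.
#' @param v_large [volume3d] of the same shape, filtered with the large
#'   patch radius.
#' @param lll_from which input contributes the approximation band
#'   (default `"large"`).
#' @return The mixed [volume3d].
#' @export
subband_mix <- function(v_small, v_large,
                        lll_from = c("large", "small")) {
  lll_from <- match.arg(lll_from)
  ds <- if (is_volume3d(v_small)) dim(v_small$data) else dim(v_small)
  dl <- if (is_volume3d(v_large)) dim(v_large$data) else dim(v_large)
  if (!identical(ds, dl)) stop("'v_small' and 'v_large' must have the same shape")
  ss <- dwt3(v_small)
  sl <- dwt3(v_large)
  mixed <- if (lll_from == "large") ss else sl
  mixed$LLL <- (if (lll_from == "large") sl else ss)$LLL
  idwt3(mixed)
}
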