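#' Construct a 3-D fluence volume
#'
#' `volume3d` is the canonical in-memory container consumed and produced by
#' every filter, simulator and metric in the package: a 3-D array of
#' non-negative scalar fluence values together with the physical voxel size
#' and a flag recording whether values are raw (linear) fluence or
#' log10-fluence used for display.
#'
#' The in-memory axis order is `(x, y, z)` with `x` the first (fastest
#' varying) index, matching the convention of voxel Monte Carlo photon
#' engines. Values are held as R doubles; file round trips through the raw
#' format quantise to 32-bit floats.
#'
#' @param data numeric 3-D array (or a vector plus `dim`) of fluence values.
#' @param voxel_size physical voxel edge length per axis in mm; scalar or
#'   length-3, recycled to length 3.
#' @param scale `"linear"` for raw fluence (all finite values must be
#'   non-negative) or `"log10"` for log10-transformed display values.
#' @param dim optional dimensions when `data` is given as a plain vector.
#' @return An object of class `volume3d`: a list with elements `data`
#'   (3-D array), `voxel_size` (length-3 numeric, mm) and `scale`.
#' @examples
#' v <- volume3d(array(1, c(4, 4, 4)))
#' dim(v$data)
#' @export
volume3d <- function(data, voxel_size = 1, scale = c("linear", "log10"),
                     dim = NULL) {
  scale <- match.arg(scale)
  if (!is.null(dim)) dim(data) <- dim
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (any(dim(data) < 1L)) stop("all three extents must be >= 1")
  storage.mode(data) <- "double"
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be positive and finite")
  if (scale == "linear") {
    fin <- data[is.finite(data)]
    if (length(fin) && any(fin < 0))
      stop("linear-scale fluence must be non-negative")
  }
  structure(list(data = data, voxel_size = voxel_size, scale = scale),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, %s scale\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$scale))
  fin <- x$data[is.finite(x$data)]
  if (length(fin))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
                min(fin), max(fin), mean(fin)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
as.array.volume3d <- function(x, ...) x$data

is_volume3d <- function(x) inherits(x, "volume3d")

assert_volume3d <- function(x, arg = deparse(substitute(x))) {
  if (!is_volume3d(x)) stop(sprintf("'%s' must be a volume3d object", arg))
  invisible(x)
}

#' Read a headerless float32 raw volume
#'
#' Reads the raw little-endian 32-bit float binary dialect emitted by voxel
#' Monte Carlo photon engines (".mc2"-style files). The file carries no
#' header, so the grid shape must be supplied.
#'
#' @param path file to read.
#' @param shape integer vector of three positive extents `(Nx, Ny, Nz)`.
#' @param order `"first-axis-fastest"` (default; x varies fastest on disk,
#'   the MC-engine convention) or `"last-axis-fastest"`.
#' @param voxel_size voxel edge length in mm (metadata only; the raw format
#'   does not store it).
#' @param scale value scale recorded on the returned volume.
#' @return A [volume3d] with `data` of dimension `shape`.
#' @seealso [write_raw_volume()]
#' @export
read_raw_volume <- function(path, shape,
                            order = c("first-axis-fastest",
                                      "last-axis-fastest"),
                            voxel_size = 1, scale = "linear") {
  order <- match.arg(order)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three positive integers")
  n <- prod(shape)
  expected <- n * 4
  actual <- file.size(path)
  if (is.na(actual)) stop(sprintf("cannot stat '%s'", path))
  if (actual != expected)
    stop(sprintf(
      "raw volume size mismatch for '%s': expected %d bytes (%d x %d x %d float32), found %d",
      path, expected, shape[1], shape[2], shape[3], actual))
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = n, size = 4L,
                  endian = "little")
  if (order == "first-axis-fastest") {
    arr <- array(vals, dim = shape)
  } else {
    arr <- aperm(array(vals, dim = rev(shape)), c(3L, 2L, 1L))
  }
  volume3d(arr, voxel_size = voxel_size, scale = scale)
}

#' Write a headerless float32 raw volume
#'
#' @param v a [volume3d].
#' @param path output file.
#' @param order on-disk axis order; see [read_raw_volume()].
#' @return Invisibly, `path`.
#' @export
write_raw_volume <- function(v, path,
                             order = c("first-axis-fastest",
                                       "last-axis-fastest")) {
  assert_volume3d(v)
  order <- match.arg(order)
  arr <- v$data
  if (order == "last-axis-fastest") arr <- aperm(arr, c(3L, 2L, 1L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read / write NIfTI-1 volumes
#'
#' Thin adapters between [volume3d] and single-file NIfTI-1 images, for
#' interoperability with MRI tooling. Voxel sizes are taken from (written
#' to) the header pixdim zooms.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param scale value scale recorded on the volume read.
#' @return `read_nifti` returns a [volume3d]; `write_nifti` invisibly
#'   returns `path`.
#' @export
read_nifti <- function(path, scale = "linear") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D NIfTI volume, got %d dimensions",
                 length(d)))
  arr <- array(as.vector(as.array(img)), dim = d)
  vox <- RNifti::pixdim(img)[seq_len(3L)]
  volume3d(arr, voxel_size = vox, scale = scale)
}

#' @param v a [volume3d] to write.
#' @rdname read_nifti
#' @export
write_nifti <- function(v, path) {
  assert_volume3d(v)
  img <- RNifti::asNifti(structure(v$data, pixdim = v$voxel_size),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}
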