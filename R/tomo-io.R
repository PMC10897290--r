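# Volume and image containers, MRC I/O, projection, contrast normalization.

#' Tomogram container
#'
#' A tomogram is a 3D grayscale volume with a physical voxel size.  Arrays are
#' indexed `[x, y, z]` (1-based, x fastest, matching MRC on-disk order); the
#' electron beam runs along z and the tilt axis along y.
#'
#' @param data numeric 3D array.
#' @param voxel_size_nm voxel edge length in nanometres (> 0).
#' @param origin integer voxel offset triple (bookkeeping only).
#' @param meta free-form provenance list.
#' @return an object of class `tomogram`.
#' @export
tomogram <- function(data, voxel_size_nm, origin = c(0L, 0L, 0L), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L || voxel_size_nm <= 0)
    stopf("`voxel_size_nm` must be a single positive number")
  if (anyNA(data) || any(!is.finite(data)))
    stopf("tomogram data must be finite")
  structure(
    list(data = data, voxel_size_nm = voxel_size_nm, origin = origin, meta = meta),
    class = "tomogram"
  )
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomogram> %d x %d x %d voxels @ %.4g nm/voxel (%.3g x %.3g x %.3g nm)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              d[1] * x$voxel_size_nm, d[2] * x$voxel_size_nm, d[3] * x$voxel_size_nm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' 2D image container
#'
#' @param data numeric matrix.
#' @param pixel_size_nm pixel edge length in nanometres (> 0).
#' @return an object of class `image2d`.
#' @export
image2d <- function(data, pixel_size_nm) {
  if (!is.matrix(data)) stopf("`data` must be a matrix")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L || pixel_size_nm <= 0)
    stopf("`pixel_size_nm` must be a single positive number")
  structure(list(data = data, pixel_size_nm = pixel_size_nm), class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image2d> %d x %d px @ %.4g nm/px\n", d[1], d[2], x$pixel_size_nm))
  invisible(x)
}

# ---------------------------------------------------------------------------
# MRC (MRC2014, mode 2 float32)

#' Write a tomogram to an MRC file
#'
#' Writes MRC2014 mode 2 (float32) with the voxel size recorded in the cell
#' dimensions (Angstrom).
#'
#' @param tomo a [tomogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(tomo, path) {
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$data)
  apix <- tomo$voxel_size_nm * 10   # nm -> Angstrom
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2L)                                  # mode 2 = float32
  wi(c(0L, 0L, 0L))                       # nxstart
  wi(d)                                   # mx my mz
  wf(d * apix)                            # cella (A)
  wf(c(90, 90, 90))                       # cellb
  wi(c(1L, 2L, 3L))                       # mapc mapr maps
  wf(c(min(tomo$data), max(tomo$data), mean(tomo$data)))
  wi(0L)                                  # ispg
  wi(0L)                                  # nsymbt
  wi(rep(0L, 2))                          # extra words 26-27
  writeChar("MRC ", con, 4, eos = NULL)   # exttyp (word 28 region start)
  wi(20140L)                              # nversion
  wi(rep(0L, 21))                         # remaining extra
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(tomo$data))                # rms
  wi(0L)                                  # nlabl
  writeBin(raw(800L), con)                # labels
  writeBin(as.numeric(tomo$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a tomogram from an MRC file
#'
#' Supports MRC mode 2 (float32).  The voxel size is taken from the cell
#' dimensions and converted from Angstrom to nanometres.
#'
#' @param path MRC file path.
#' @return a [tomogram()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  hdr_dim <- ri(3)
  mode <- ri(1)
  if (length(mode) != 1L || anyNA(hdr_dim) || length(hdr_dim) != 3L)
    stopf("malformed MRC header in %s", path)
  if (any(hdr_dim <= 0) || any(hdr_dim > 1e5))
    stopf("malformed MRC header in %s (implausible dimensions)", path)
  if (mode != 2L)
    stopf("unsupported MRC mode %d in %s (only mode 2 float32 is supported)", mode, path)
  ri(3)                 # nxstart
  m <- ri(3)            # mx my mz
  cella <- rf(3)
  seek(con, 1024L)
  n <- prod(hdr_dim)
  dat <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(dat) != n)
    stopf("truncated MRC file %s: expected %d voxels, got %d", path, n, length(dat))
  grid <- ifelse(m > 0, m, hdr_dim)
  apix <- cella[1] / grid[1]
  if (!is.finite(apix) || apix <= 0) apix <- 1
  tomogram(array(dat, dim = hdr_dim), voxel_size_nm = apix / 10,
           meta = list(source = path))
}

# ---------------------------------------------------------------------------
# Projection and contrast

#' Summed projection of tomogram slices
#'
#' Sums `n_slices` consecutive z-slices centred on `z_center`, mirroring the
#' summed projection images used for projection-plane measurements.
#'
#' @param tomo a [tomogram()].
#' @param z_center central slice index (1-based).  Defaults to the mid-slice.
#' @param n_slices number of slices in the window (default 10).
#' @return an [image2d()] whose pixel value is the sum over the window.
#' @export
summed_projection <- function(tomo, z_center = NULL, n_slices = 10L) {
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$data)
  if (is.null(z_center)) z_center <- ceiling(d[3] / 2)
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stopf("`n_slices` must be >= 1")
  z0 <- as.integer(z_center) - (n_slices - 1L) %/% 2L
  zs <- z0 + seq_len(n_slices) - 1L
  if (min(zs) < 1L || max(zs) > d[3])
    stopf("slice window [%d, %d] out of bounds (volume has %d slices)",
          min(zs), max(zs), d[3])
  img <- apply(tomo$data[, , zs, drop = FALSE], c(1, 2), sum)
  image2d(img, pixel_size_nm = tomo$voxel_size_nm)
}

#' Saturated linear contrast normalization
#'
#' Linearly rescales intensities to `[0, 1]` after clipping the lowest and
#' highest `saturation_fraction / 2` quantiles, the convention used to put
#' projection images of different tomograms on a comparable gray scale before
#' density measurements.  A constant image maps to all zeros.
#'
#' @param image an [image2d()].
#' @param saturation_fraction total fraction of pixels saturated (default
#'   0.0035, i.e. 0.35% split evenly between the two tails).
#' @return a contrast-normalized [image2d()].
#' @export
normalize_contrast <- function(image, saturation_fraction = 0.0035) {
  stopifnot(inherits(image, "image2d"))
  if (!is.numeric(saturation_fraction) || length(saturation_fraction) != 1L ||
      saturation_fraction < 0 || saturation_fraction >= 1)
    stopf("`saturation_fraction` must be in [0, 1)")
  x <- image$data
  if (length(x) == 0L) stopf("image is empty")
  qs <- stats::quantile(x, c(saturation_fraction / 2, 1 - saturation_fraction / 2),
                        names = FALSE, type = 7)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) {
    image$data <- array(0, dim = dim(x))
    return(image)
  }
  y <- (pmin(pmax(x, lo), hi) - lo) / (hi - lo)
  image$data <- y
  image
}
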