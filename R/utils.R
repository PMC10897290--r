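# Internal helpers: seeded evaluation, geometry, interpolation.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global random stream set from `seed`, then restores
#' whatever random state existed before the call, so package functions never
#' leak RNG state into the caller's session.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and a stream index, kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("zero-length vector cannot be normalized", call. = FALSE)
  v / n
}

## Angle between two vectors, degrees in [0, 180].
angle_between <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

## Rotation matrix mapping the +z axis onto unit vector `dir` (columns are the
## rotated frame axes).  Any in-plane convention is acceptable for slab work.
rotation_to_z <- function(dir) {
  w <- unit(dir)
  ref <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(pracma_cross(ref, w))
  v <- pracma_cross(w, u)
  cbind(u, v, w)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Rotation about an axis by angle (degrees), Rodrigues form.
rotation_axis_angle <- function(axis, angle_deg) {
  k <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Coordinate arrays (nm) for a voxel grid; voxel centres at (i - 0.5) * vox.
coord_arrays <- function(dim, voxel_size_nm) {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  xv <- (seq_len(nx) - 0.5) * voxel_size_nm
  yv <- (seq_len(ny) - 0.5) * voxel_size_nm
  zv <- (seq_len(nz) - 0.5) * voxel_size_nm
  list(
    x = array(xv, dim),
    y = array(rep(yv, each = nx), dim),
    z = array(rep(zv, each = nx * ny), dim)
  )
}

## Trilinear interpolation of a 3D array at fractional voxel coordinates
## (1-based).  Out-of-volume samples return `fill`.
interp3 <- function(vol, xi, yi, zi, fill = 0) {
  d <- dim(vol)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  ok <- x0 >= 1 & x0 <= d[1] - 1 & y0 >= 1 & y0 <= d[2] - 1 & z0 >= 1 & z0 <= d[3] - 1
  out <- rep(fill, length(xi))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
  v000 <- vol[idx(x0, y0, z0)];     v100 <- vol[idx(x0 + 1, y0, z0)]
  v010 <- vol[idx(x0, y0 + 1, z0)]; v110 <- vol[idx(x0 + 1, y0 + 1, z0)]
  v001 <- vol[idx(x0, y0, z0 + 1)]; v101 <- vol[idx(x0 + 1, y0, z0 + 1)]
  v011 <- vol[idx(x0, y0 + 1, z0 + 1)]; v111 <- vol[idx(x0 + 1, y0 + 1, z0 + 1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

## Rotate a cubic volume about its centre by rotation matrix R (frame mapping:
## sample the input at R %*% x for each output coordinate x), trilinear.
rotate_volume <- function(vol, R, fill = 0) {
  d <- dim(vol)
  ctr <- (d + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  p <- t(R %*% rbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3]))
  array(interp3(vol, p[, 1] + ctr[1], p[, 2] + ctr[2], p[, 3] + ctr[3], fill = fill), d)
}

## Circular shift of a 3D array by integer offsets (value at x appears at x+s).
shift_volume <- function(vol, s) {
  d <- dim(vol)
  ix <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  iy <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  iz <- ((seq_len(d[3]) - 1 - s[3]) %% d[3]) + 1
  vol[ix, iy, iz, drop = FALSE]
}

## Soft spherical mask: 1 inside radius, cosine falloff over `soft` voxels.
soft_spherical_mask <- function(box, radius = 0.45 * box, soft = 3) {
  ctr <- (box + 1) / 2
  v <- seq_len(box) - ctr
  r <- sqrt(outer(outer(v^2, v^2, `+`), v^2, `+`))
  m <- array(0, dim = c(box, box, box))
  m[r <= radius] <- 1
  band <- r > radius & r < radius + soft
  m[band] <- 0.5 * (1 + cos(pi * (r[band] - radius) / soft))
  m
}

## FFT frequency index vector in cycles per sample.
fft_freq <- function(n) {
  k <- seq_len(n) - 1
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

## Mask-weighted mean/variance standardization; returns standardized values.
mask_standardize <- function(x, w) {
  sw <- sum(w)
  mu <- sum(w * x) / sw
  s2 <- sum(w * (x - mu)^2) / sw
  if (s2 <= .Machine$double.eps) return(list(z = x * 0, sd = 0, mean = mu))
  list(z = (x - mu) / sqrt(s2), sd = sqrt(s2), mean = mu)
}

## Masked zero-mean normalized cross-correlation of two equally-sized arrays.
masked_ncc <- function(a, b, mask) {
  za <- mask_standardize(a, mask)
  zb <- mask_standardize(b, mask)
  if (za$sd == 0 || zb$sd == 0) return(0)
  sum(mask * za$z * zb$z) / sum(mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
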