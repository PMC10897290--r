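# Template-bank width estimation and miniature subtomogram alignment/averaging.
#
# Crista width is called per particle by masked zero-mean normalized
# cross-correlation against a bank of two-membrane templates whose
# centre-to-centre separations step through integer pixels; the separation of
# the best-matching template is the width.  Because the templates are
# laterally constant slabs, the 3D masked NCC against a template reduces
# exactly to a weighted 1D correlation of mask-reduced axial profiles, which
# is what the estimator computes.

#' Build a two-membrane template bank
#'
#' Template `k` holds two parallel membrane slabs (the same anti-aliased
#' profile as phantom membranes, dark on light) whose centre-to-centre
#' separation is exactly `k` pixels, centred in the box with normals along z.
#' Each template is normalized to zero mean.  The defaults span 2.2 nm to
#' 88 nm in 40 steps of 2.2 nm.
#'
#' @param n_templates number of templates (default 40).
#' @param pixel_size_nm pixel size of the width frame (default 2.2).
#' @param box template box edge in voxels (default 48, i.e. 105.6 nm).
#' @param membrane_thickness_nm membrane slab thickness (default 5 nm).
#' @param mask_radius_frac soft spherical mask radius as a fraction of the box
#'   (default 0.45).
#' @return an object of class `template_bank`.
#' @export
template_bank <- function(n_templates = 40L, pixel_size_nm = 2.2, box = 48L,
                          membrane_thickness_nm = 5,
                          mask_radius_frac = 0.45) {
  n_templates <- as.integer(n_templates)
  box <- as.integer(box)
  if (n_templates < 1L) stopf("`n_templates` must be >= 1")
  th_px <- membrane_thickness_nm / pixel_size_nm
  if (n_templates + th_px >= box - 1)
    stopf("maximum separation (%d px) plus membrane does not fit in a %d-voxel box",
          n_templates, box)
  zc <- (box + 1) / 2
  profiles <- matrix(0, nrow = box, ncol = n_templates)
  for (k in seq_len(n_templates)) {
    cov <- two_slab_coverage(seq_len(box), centers = zc + c(-k / 2, k / 2),
                             thickness = th_px)
    p <- -cov                      # membranes dark; solvent level 0
    profiles[, k] <- p - mean(p)   # bank normalization: zero mean
  }
  structure(list(
    n_templates = n_templates, pixel_size_nm = pixel_size_nm, box = box,
    membrane_thickness_nm = membrane_thickness_nm,
    separations_px = seq_len(n_templates),
    separations_nm = seq_len(n_templates) * pixel_size_nm,
    profiles = profiles,
    mask = soft_spherical_mask(box, radius = mask_radius_frac * box)
  ), class = "template_bank")
}

## 1D coverage of voxel [z - 0.5, z + 0.5] by the union of two slabs.
two_slab_coverage <- function(z, centers, thickness) {
  h <- thickness / 2
  lo1 <- centers[1] - h; hi1 <- centers[1] + h
  lo2 <- centers[2] - h; hi2 <- centers[2] + h
  ov <- function(lo, hi) pmax(0, pmin(z + 0.5, hi) - pmax(z - 0.5, lo))
  if (lo2 <= hi1) {                       # slabs merge
    ov(lo1, hi2)
  } else {
    ov(lo1, hi1) + ov(lo2, hi2)
  }
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d templates, box %d^3 @ %.3g nm/px, separations %.3g-%.3g nm\n",
              x$n_templates, x$box, x$pixel_size_nm,
              min(x$separations_nm), max(x$separations_nm)))
  invisible(x)
}

#' Materialize one bank template as a 3D volume
#'
#' @param bank a [template_bank()].
#' @param k template index.
#' @return a `box^3` array (zero mean, membranes dark, normals along z).
#' @export
template_volume <- function(bank, k) {
  stopifnot(inherits(bank, "template_bank"))
  if (k < 1 || k > bank$n_templates) stopf("template index %d out of range", k)
  array(rep(bank$profiles[, k], each = bank$box^2), rep(bank$box, 3))
}

# ---------------------------------------------------------------------------
# Particle extraction

#' Extract subtomograms at picked positions
#'
#' Copies `box^3` subvolumes centred on each position.  Positions whose box
#' crosses the volume boundary are dropped with a warning and counted.  When a
#' membrane normal accompanies a position, the subvolume is brought into the
#' template frame (normal along +z): axis-aligned normals use an exact axis
#' permutation, oblique normals a trilinear rotation.
#'
#' @param tomo a [tomogram()].
#' @param positions data.frame with voxel coordinates `x, y, z` and optional
#'   normals `nx, ny, nz` (e.g. from [sample_particles()]).
#' @param box box edge in voxels (default 48).
#' @param rotate_to_frame bring subvolumes into the template frame using the
#'   recorded normals (default TRUE).
#' @return an object of class `particle_set`.
#' @export
extract_subtomograms <- function(tomo, positions, box = 48L,
                                 rotate_to_frame = TRUE) {
  stopifnot(inherits(tomo, "tomogram"))
  box <- as.integer(box)
  d <- dim(tomo$data)
  half_lo <- box %/% 2L - 1L    # centre voxel has (box/2 - 1) below, box/2 above
  half_hi <- box - 1L - half_lo
  has_normal <- all(c("nx", "ny", "nz") %in% names(positions))
  subs <- list(); keep <- logical(nrow(positions))
  for (i in seq_len(nrow(positions))) {
    c0 <- round(c(positions$x[i], positions$y[i], positions$z[i]))
    lo <- c0 - half_lo; hi <- c0 + half_hi
    if (any(lo < 1) || any(hi > d)) next
    sv <- tomo$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    if (has_normal && rotate_to_frame) {
      nrm <- c(positions$nx[i], positions$ny[i], positions$nz[i])
      sv <- orient_to_z(sv, nrm)
    }
    keep[i] <- TRUE
    subs[[length(subs) + 1L]] <- sv
  }
  dropped <- sum(!keep)
  if (dropped > 0L)
    warning(sprintf("%d particle(s) dropped: box crosses the volume boundary", dropped))
  pos <- positions[keep, , drop = FALSE]
  rownames(pos) <- NULL
  structure(list(subvolumes = subs, positions = pos, box = box,
                 pixel_size_nm = tomo$voxel_size_nm, dropped = dropped),
            class = "particle_set")
}

## Bring a subvolume's membrane normal onto +z.  Axis-aligned normals are an
## exact permutation/flip; anything else is interpolated.
orient_to_z <- function(sv, nrm) {
  nrm <- unit(nrm)
  ax <- which(abs(abs(nrm) - 1) < 1e-9)
  if (length(ax) == 1L) {
    sv <- switch(ax,
                 aperm(sv, c(3, 2, 1)),   # x -> z
                 aperm(sv, c(1, 3, 2)),   # y -> z
                 sv)
    if (nrm[ax] < 0) sv <- sv[, , dim(sv)[3]:1, drop = FALSE]
    sv
  } else {
    rotate_volume(sv, rotation_to_z(nrm))
  }
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, box %d^3 @ %.3g nm/px (%d dropped at boundary)\n",
              length(x$subvolumes), x$box, x$pixel_size_nm, x$dropped))
  if (!is.null(x$positions$width_nm))
    cat(sprintf("  widths estimated: median %.3g nm\n",
                stats::median(x$positions$width_nm)))
  invisible(x)
}

#' @export
length.particle_set <- function(x) length(x$subvolumes)

# ---------------------------------------------------------------------------
# Width estimation

#' Estimate crista width for one particle
#'
#' Computes, for every bank template, the maximum masked zero-mean normalized
#' cross-correlation over axial shifts (and optionally over a coarse-then-fine
#' orientation search), and returns the separation of the best-matching
#' template as the width.  Ties break toward the smaller separation.
#'
#' @param particle a `box^3` numeric array in the template frame (membrane
#'   normal along z), or a single-element subset of a `particle_set`.
#' @param bank a [template_bank()].
#' @param refine_orientation search membrane orientation (15 degree hemisphere
#'   grid then 3 degree local refinement) before matching (default FALSE;
#'   particles extracted with recorded normals are already in frame).
#' @param shift_bound_px maximum axial shift searched (default 4).
#' @return a list with `width_nm`, `cc_peak`, `template_index`, `shift_px`,
#'   and the per-template score vector `cc_by_template`.
#' @export
estimate_width <- function(particle, bank, refine_orientation = FALSE,
                           shift_bound_px = 4L) {
  stopifnot(inherits(bank, "template_bank"))
  if (inherits(particle, "particle_set")) {
    if (length(particle$subvolumes) != 1L)
      stopf("pass a single particle; use estimate_widths() for a set")
    if (abs(particle$pixel_size_nm - bank$pixel_size_nm) > 1e-9)
      stopf("particle pixel size (%.4g nm) does not match bank (%.4g nm)",
            particle$pixel_size_nm, bank$pixel_size_nm)
    particle <- particle$subvolumes[[1]]
  }
  if (!is.array(particle) || !all(dim(particle) == bank$box))
    stopf("particle box %s does not match bank box %d",
          paste(dim(particle), collapse = "x"), bank$box)
  if (refine_orientation) {
    R <- find_membrane_orientation(particle, bank$mask)
    particle <- rotate_volume(particle, R)
  }
  red <- profile_reduce(particle, bank$mask)
  score_templates(red, bank, shift_bound_px)
}

## Mask-reduced axial statistics of a volume:
##   w(z) = sum_xy mask, q(z) = sum_xy mask * vol, s(z) = sum_xy mask * vol^2.
profile_reduce <- function(vol, mask) {
  box <- dim(vol)[3]
  mz <- matrix(mask, ncol = box)
  vz <- matrix(vol, ncol = box)
  w <- colSums(mz)
  q <- colSums(mz * vz)
  s <- colSums(mz * vz * vz)
  sw <- sum(w)
  mu <- sum(q) / sw
  var_v <- (sum(s) - 2 * mu * sum(q) + mu^2 * sw) / sw
  list(w = w, q = q, mu = mu, sd = sqrt(max(var_v, 0)), sw = sw)
}

score_templates <- function(red, bank, shift_bound_px) {
  box <- bank$box
  shifts <- -as.integer(shift_bound_px):as.integer(shift_bound_px)
  resid <- red$q - red$mu * red$w           # w(z) * (mean profile - mu)
  cc_by_template <- numeric(bank$n_templates)
  best_shift <- integer(bank$n_templates)
  if (red$sd <= 0) {
    return(list(width_nm = bank$separations_nm[1], cc_peak = 0,
                template_index = 1L, shift_px = 0L,
                cc_by_template = cc_by_template))
  }
  for (k in seq_len(bank$n_templates)) {
    p <- bank$profiles[, k]
    best <- -Inf; bs <- 0L
    for (s in shifts) {
      idx <- ((seq_len(box) - 1 - s) %% box) + 1
      ps <- p[idx]
      mup <- sum(red$w * ps) / red$sw
      sdp <- sqrt(max(sum(red$w * (ps - mup)^2) / red$sw, 0))
      if (sdp <= 0) next
      cc <- sum((ps - mup) * resid) / (red$sw * sdp * red$sd)
      if (cc > best) { best <- cc; bs <- s }
    }
    cc_by_template[k] <- best
    best_shift[k] <- bs
  }
  kbest <- which.max(cc_by_template)        # ties resolve to smaller separation
  list(width_nm = bank$separations_nm[kbest],
       cc_peak = cc_by_template[kbest],
       template_index = kbest,
       shift_px = best_shift[kbest],
       cc_by_template = cc_by_template)
}

#' Estimate widths for every particle in a set
#'
#' @param particles a `particle_set`.
#' @param bank a [template_bank()].
#' @inheritParams estimate_width
#' @return the `particle_set` with `width_nm`, `cc_peak` and `template_index`
#'   columns added to its `positions` table.
#' @export
estimate_widths <- function(particles, bank, refine_orientation = FALSE,
                            shift_bound_px = 4L) {
  stopifnot(inherits(particles, "particle_set"))
  if (abs(particles$pixel_size_nm - bank$pixel_size_nm) > 1e-9)
    stopf("particle pixel size (%.4g nm) does not match bank (%.4g nm)",
          particles$pixel_size_nm, bank$pixel_size_nm)
  n <- length(particles$subvolumes)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- estimate_width(particles$subvolumes[[i]], bank,
                               refine_orientation = refine_orientation,
                               shift_bound_px = shift_bound_px)
  }
  particles$positions$width_nm <- vapply(res, `[[`, numeric(1), "width_nm")
  particles$positions$cc_peak <- vapply(res, `[[`, numeric(1), "cc_peak")
  particles$positions$template_index <-
    vapply(res, `[[`, integer(1), "template_index")
  particles
}

## Orientation scoring: a membrane stack aligned to z maximizes the axial
## variance of the mask-reduced mean profile.
find_membrane_orientation <- function(vol, mask, coarse_deg = 15, fine_deg = 3) {
  score <- function(R) {
    v <- rotate_volume(vol, R)
    red <- profile_reduce(v, mask)
    pz <- ifelse(red$w > 0, red$q / pmax(red$w, 1e-12), red$mu)
    stats::var(pz[red$w > 0])
  }
  dirs <- hemisphere_directions(coarse_deg)
  sc <- apply(dirs, 1, function(d) score(t(rotation_to_z(d))))
  best <- dirs[which.max(sc), ]
  # local refinement around the best coarse direction
  fine <- local_directions(best, within_deg = coarse_deg, step_deg = fine_deg)
  scf <- apply(fine, 1, function(d) score(t(rotation_to_z(d))))
  t(rotation_to_z(fine[which.max(scf), ]))
}

## Hemisphere grid of unit directions at roughly uniform angular spacing.
hemisphere_directions <- function(step_deg) {
  thetas <- seq(0, 90, by = step_deg)
  out <- list(c(0, 0, 1))
  for (th in thetas[-1]) {
    nphi <- max(1L, ceiling(360 * sin(th * pi / 180) / step_deg))
    phis <- seq(0, 360 - 360 / nphi, by = 360 / nphi)
    for (ph in phis) {
      t_ <- th * pi / 180; p_ <- ph * pi / 180
      out[[length(out) + 1L]] <- c(sin(t_) * cos(p_), sin(t_) * sin(p_), cos(t_))
    }
  }
  do.call(rbind, out)
}

local_directions <- function(center, within_deg, step_deg) {
  dirs <- hemisphere_directions(step_deg)
  dirs <- rbind(dirs, -dirs)
  keep <- apply(dirs, 1, function(d) angle_between(d, center) <= within_deg)
  rbind(center, dirs[keep, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Alignment and averaging

#' Iterative subtomogram alignment and averaging
#'
#' Builds an initial reference from a seeded random subset of (unaligned)
#' particles, then iteratively shifts (and optionally rotates) each particle
#' to maximize the masked zero-mean normalized cross-correlation against the
#' current reference, re-averaging after each pass.  Stops at `n_iter`
#' (default 12) or when no particle's alignment changes.
#'
#' @param particles a `particle_set` with at least 2 usable particles.
#' @param n_iter maximum iterations (default 12).
#' @param angular_step_deg orientation search step in degrees, or `NULL`
#'   (default) for translation-only alignment.
#' @param shift_bound_px maximum shift searched per axis (default 4).
#' @param seed seed for the initial-reference subset.
#' @param init_fraction fraction of particles averaged into the initial
#'   reference (default 0.5).
#' @return a list with `average` (an `average_map`: density, particle count,
#'   per-iteration mean-cc trace, convergence flag) and `particles` (the set
#'   with per-particle shifts, orientation indices and cc scores).
#' @export
align_and_average <- function(particles, n_iter = 12L, angular_step_deg = NULL,
                              shift_bound_px = 4L, seed = 1L,
                              init_fraction = 0.5) {
  stopifnot(inherits(particles, "particle_set"))
  subs <- particles$subvolumes
  usable <- vapply(subs, function(s) stats::sd(s) > 0, logical(1))
  if (any(!usable)) {
    warning(sprintf("%d all-constant particle(s) excluded from alignment",
                    sum(!usable)))
    subs <- subs[usable]
  }
  n <- length(subs)
  if (n < 2L) stopf("alignment requires at least 2 usable particles")
  box <- particles$box
  mask <- soft_spherical_mask(box)
  dirs <- if (!is.null(angular_step_deg)) hemisphere_directions(angular_step_deg)
          else matrix(c(0, 0, 1), 1)

  n_init <- max(2L, ceiling(init_fraction * n))
  init_idx <- with_seed(seed, sample.int(n, n_init))
  ref <- Reduce(`+`, subs[init_idx]) / n_init

  shifts <- matrix(0L, n, 3)
  oris <- rep(1L, n)
  ccs <- numeric(n)
  trace <- numeric(0)
  converged <- FALSE
  fft_refm <- NULL

  fft_mask <- stats::fft(mask)
  msum <- sum(mask)

  for (it in seq_len(n_iter)) {
    zr <- mask_standardize(ref, mask)
    A <- mask * zr$z
    fft_A <- stats::fft(A)
    den_ref <- sqrt(sum(mask * zr$z^2))
    new_shifts <- shifts; new_oris <- oris
    rotated <- vector("list", n)
    for (i in seq_len(n)) {
      best_cc <- -Inf; best_s <- c(0L, 0L, 0L); best_o <- 1L; best_vol <- NULL
      for (o in seq_len(nrow(dirs))) {
        v <- if (nrow(dirs) == 1L || o == 1L) subs[[i]]
             else rotate_volume(subs[[i]], t(rotation_to_z(dirs[o, ])))
        sr <- masked_ncc_shift(v, fft_A, fft_mask, msum, den_ref,
                               shift_bound_px)
        cc <- sr$cc; s <- sr$shift
        if (cc > best_cc) {
          best_cc <- cc; best_s <- s; best_o <- o; best_vol <- v
        }
      }
      new_shifts[i, ] <- best_s; new_oris[i] <- best_o
      ccs[i] <- best_cc
      rotated[[i]] <- best_vol
    }
    trace <- c(trace, mean(ccs))
    # anchor the common frame: remove any net drift of the shift ensemble
    drift <- round(colMeans(new_shifts))
    if (any(drift != 0)) new_shifts <- sweep(new_shifts, 2, drift)
    aligned <- lapply(seq_len(n), function(i)
      shift_volume(rotated[[i]], new_shifts[i, ]))
    ref <- Reduce(`+`, aligned) / n
    unchanged <- all(new_shifts == shifts) && all(new_oris == oris)
    shifts <- new_shifts; oris <- new_oris
    if (unchanged) { converged <- TRUE; break }
  }

  pos <- particles$positions[usable, , drop = FALSE]
  pos$shift_x <- shifts[, 1]; pos$shift_y <- shifts[, 2]; pos$shift_z <- shifts[, 3]
  pos$orientation <- oris
  pos$cc <- ccs
  particles$positions <- pos
  particles$subvolumes <- subs
  avg <- structure(list(density = ref, n_particles = n, cc_trace = trace,
                        converged = converged, box = box,
                        pixel_size_nm = particles$pixel_size_nm),
                   class = "average_map")
  list(average = avg, particles = particles)
}

#' @export
print.average_map <- function(x, ...) {
  cat(sprintf("<average_map> %d particles, box %d^3, %d iteration(s), final mean cc %.4f%s\n",
              x$n_particles, x$box, length(x$cc_trace),
              utils::tail(x$cc_trace, 1), if (x$converged) " (converged)" else ""))
  invisible(x)
}

## Exact masked zero-mean normalized cross-correlation over all integer
## shifts inside a cube bound (the per-shift statistics of the moving volume
## under the fixed mask are computed by FFT, so the value at the returned
## shift equals masked_ncc of the shifted volume).
masked_ncc_shift <- function(vol, fft_A, fft_mask, msum, den_ref, bound) {
  d <- dim(vol)
  np <- prod(d)
  fv <- Conj(stats::fft(vol))
  fv2 <- Conj(stats::fft(vol * vol))
  num <- Re(stats::fft(fft_A * fv, inverse = TRUE)) / np
  s1 <- Re(stats::fft(fft_mask * fv, inverse = TRUE)) / np
  s2 <- Re(stats::fft(fft_mask * fv2, inverse = TRUE)) / np
  den_v <- sqrt(pmax(s2 - s1^2 / msum, 0))
  cc <- num / (den_v * den_ref)
  cc[den_v <= 1e-12 * sqrt(msum)] <- 0
  offs <- -as.integer(bound):as.integer(bound)
  ix <- (offs %% d[1]) + 1; iy <- (offs %% d[2]) + 1; iz <- (offs %% d[3]) + 1
  sub <- cc[ix, iy, iz, drop = FALSE]
  w <- which.max(sub)
  k <- arrayInd(w, dim(sub))
  list(shift = c(offs[k[1]], offs[k[2]], offs[k[3]]), cc = max(sub))
}

#' Measure the width of a subtomogram average
#'
#' Applies the same template-bank estimator to an average map.
#'
#' @param average an `average_map` from [align_and_average()].
#' @param bank a [template_bank()].
#' @inheritParams estimate_width
#' @return as [estimate_width()].
#' @export
measure_average_width <- function(average, bank, refine_orientation = FALSE,
                                  shift_bound_px = 4L) {
  stopifnot(inherits(average, "average_map"))
  estimate_width(average$density, bank, refine_orientation = refine_orientation,
                 shift_bound_px = shift_bound_px)
}

# ---------------------------------------------------------------------------
# Tables and histograms

#' Per-particle width table
#'
#' @param particles a `particle_set` whose widths have been estimated with
#'   [estimate_widths()].
#' @param group_label group (cell line / condition) label for the rows.
#' @return a data.frame with one row per particle: group, particle id, width
#'   (nm) and cross-correlation peak.
#' @export
width_table <- function(particles, group_label) {
  stopifnot(inherits(particles, "particle_set"))
  if (is.null(particles$positions$width_nm))
    stopf("widths not estimated yet; run estimate_widths() first")
  data.frame(
    group = group_label,
    particle_id = seq_len(nrow(particles$positions)),
    crista_id = particles$positions$crista_id %||%
      rep(NA_integer_, nrow(particles$positions)),
    width_nm = particles$positions$width_nm,
    cc_peak = particles$positions$cc_peak,
    stringsAsFactors = FALSE
  )
}

#' Histogram of crista widths
#'
#' Bins widths with edges at multiples of `bin_nm` (one template step by
#' default); counts always sum to the number of observations.
#'
#' @param widths numeric vector of widths (nm), nonempty.
#' @param bin_nm bin width in nm (default 2.2, one template step).
#' @return a data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
width_histogram <- function(widths, bin_nm = 2.2) {
  if (length(widths) == 0L) stopf("`widths` must be nonempty")
  if (bin_nm <= 0) stopf("`bin_nm` must be > 0")
  if (any(widths < 0)) stopf("widths must be nonnegative")
  # right-open bins [m * bin, (m + 1) * bin) with edges at multiples of bin_nm
  idx <- floor(widths / bin_nm) + 1L
  counts <- tabulate(idx, nbins = max(idx))
  data.frame(bin_lo = (seq_along(counts) - 1L) * bin_nm,
             bin_hi = seq_along(counts) * bin_nm,
             count = counts)
}
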