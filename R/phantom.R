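# Synthetic cryo-ET phantoms of mitochondria with known ground truth.
#
# A phantom renders an outer membrane (OMM), an inner boundary membrane (IBM)
# offset inward by the intermembrane spacing, and a set of cristae (membrane
# folds) of prescribed shape and lumen width.  Membranes are dark (low
# intensity), matching cryo-ET contrast.  Corruption order mirrors real
# reconstruction: geometry -> additive Gaussian noise -> missing wedge.

# Label codes shared across the package.
LABELS <- c(background = 0L, omm = 1L, ibm = 2L, crista_membrane = 3L,
            matrix = 4L, ims = 5L, cristae_lumen = 6L)

CRISTA_SHAPES <- c("lamellar", "tubular", "globular", "ring", "loop",
                   "straight_across", "split")

#' Specify a single crista
#'
#' Cristae are parameterized by their membrane-to-membrane width (the distance
#' between the centres of the two apposed membranes across the lumen), a
#' length, an optional depth (extent along the sheet for lamellar shapes), a
#' centre position and an orientation.
#'
#' @param shape one of `"lamellar"`, `"tubular"`, `"globular"`, `"ring"`,
#'   `"loop"`, `"straight_across"`, `"split"`.
#' @param width_nm membrane centre-to-centre distance across the lumen (> 0).
#' @param length_nm principal extent: slab length, cylinder length, ring or
#'   loop arc length.  Ignored for `"globular"`.
#' @param depth_nm sheet extent along the second axis for lamellar-like shapes
#'   (defaults to `length_nm`).
#' @param center_nm centre of the crista in volume coordinates (nm).
#' @param orientation unit 3-vector: sheet normal for `lamellar` /
#'   `straight_across` / `split`; cylinder axis for `tubular`; torus /
#'   extrusion axis for `ring` and `loop`.
#' @param direction optional unit 3-vector fixing the in-plane length axis
#'   (auto-chosen perpendicular to `orientation` when `NULL`).
#' @param junctions list of junctions, each `list(angle_deg =, width_nm =)`;
#'   the angle is measured against the inner boundary membrane so that a
#'   perpendicular crista scores 90 degrees.
#' @param arc_deg angular extent of a `"loop"` arc (default 180).
#' @param branch_length_nm,branch_angle_deg branch geometry for `"split"`
#'   (default: half the main length, at 60 degrees).
#' @return an object of class `crista_spec`.
#' @export
crista_spec <- function(shape, width_nm, length_nm = NULL, depth_nm = NULL,
                        center_nm = c(0, 0, 0), orientation = c(0, 0, 1),
                        direction = NULL, junctions = list(),
                        arc_deg = 180, branch_length_nm = NULL,
                        branch_angle_deg = 60) {
  shape <- match.arg(shape, CRISTA_SHAPES)
  if (!is.numeric(width_nm) || width_nm <= 0) stopf("`width_nm` must be > 0")
  if (shape != "globular" && (is.null(length_nm) || length_nm <= 0))
    stopf("`length_nm` must be > 0 for shape '%s'", shape)
  if (is.null(length_nm)) length_nm <- width_nm
  if (is.null(depth_nm)) depth_nm <- length_nm
  nj <- length(junctions)
  need <- switch(shape, ring = 0L, loop = 2L, straight_across = 2L, NA_integer_)
  if (!is.na(need) && nj != need)
    stopf("shape '%s' requires exactly %d junctions, got %d", shape, need, nj)
  for (j in junctions) {
    ang <- j$angle_deg %||% 90
    if (ang <= 0 || ang >= 180) stopf("junction angle must be in (0, 180)")
    if ((j$width_nm %||% 1) <= 0) stopf("junction width must be > 0")
  }
  structure(list(
    shape = shape, width_nm = width_nm, length_nm = length_nm,
    depth_nm = depth_nm, center_nm = center_nm, orientation = unit(orientation),
    direction = if (!is.null(direction)) unit(direction) else NULL,
    junctions = junctions, arc_deg = arc_deg,
    branch_length_nm = branch_length_nm %||% (length_nm / 2),
    branch_angle_deg = branch_angle_deg
  ), class = "crista_spec")
}

#' Specify a phantom tomogram
#'
#' @param box_shape voxel dimensions `(nx, ny, nz)`.
#' @param voxel_size_nm voxel edge (nm), default 2.2.
#' @param omm_semi_axes_nm semi-axes of the outer-membrane midsurface
#'   ellipsoid (nm).
#' @param center_nm ellipsoid centre (defaults to the volume centre).
#' @param ibm_gap_nm intermembrane spacing between the inner face of the OMM
#'   and the outer face of the IBM (default 10 nm).
#' @param cristae list of [crista_spec()] objects.
#' @param membrane_thickness_nm bilayer thickness (default 5 nm).
#' @param membrane_density,solvent_density intensity levels; membranes must be
#'   darker (lower) than solvent.
#' @param noise_sigma standard deviation of additive Gaussian noise (>= 0).
#' @param wedge_half_angle_deg missing-wedge half angle in degrees; a +/-70
#'   degree tilt range corresponds to the default 20.
#' @param smooth_sigma_vox optional extra Gaussian smoothing (voxels) applied
#'   to the noiseless density; the base render is already anti-aliased over
#'   one voxel, so the default is 0.
#' @param seed integer seed driving all randomness of the phantom.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(box_shape, voxel_size_nm = 2.2, omm_semi_axes_nm,
                         center_nm = NULL, ibm_gap_nm = 10, cristae = list(),
                         membrane_thickness_nm = 5, membrane_density = -1,
                         solvent_density = 0, noise_sigma = 0,
                         wedge_half_angle_deg = 20, smooth_sigma_vox = 0,
                         seed = 1L) {
  box_shape <- as.integer(box_shape)
  if (length(box_shape) != 3L || any(box_shape < 8L)) stopf("`box_shape` must be 3 dims >= 8")
  if (voxel_size_nm <= 0) stopf("`voxel_size_nm` must be > 0")
  if (length(omm_semi_axes_nm) != 3L || any(omm_semi_axes_nm <= 0))
    stopf("`omm_semi_axes_nm` must be 3 positive values")
  if (any(omm_semi_axes_nm <= 2 * membrane_thickness_nm))
    stopf("semi-axes must exceed twice the membrane thickness")
  if (noise_sigma < 0) stopf("`noise_sigma` must be >= 0")
  if (wedge_half_angle_deg < 0 || wedge_half_angle_deg > 90)
    stopf("`wedge_half_angle_deg` must be in [0, 90]")
  if (membrane_density >= solvent_density)
    stopf("membranes must be darker than solvent (membrane_density < solvent_density)")
  if (is.null(center_nm)) center_nm <- box_shape * voxel_size_nm / 2
  if (inherits(cristae, "crista_spec")) cristae <- list(cristae)
  structure(list(
    box_shape = box_shape, voxel_size_nm = voxel_size_nm,
    omm_semi_axes_nm = omm_semi_axes_nm, center_nm = center_nm,
    ibm_gap_nm = ibm_gap_nm, cristae = cristae,
    membrane_thickness_nm = membrane_thickness_nm,
    membrane_density = membrane_density, solvent_density = solvent_density,
    noise_sigma = noise_sigma, wedge_half_angle_deg = wedge_half_angle_deg,
    smooth_sigma_vox = smooth_sigma_vox, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d @ %.3g nm/voxel, %d crista(e), noise sd %.3g, wedge %.3g deg\n",
              x$box_shape[1], x$box_shape[2], x$box_shape[3], x$voxel_size_nm,
              length(x$cristae), x$noise_sigma, x$wedge_half_angle_deg))
  invisible(x)
}

#' Noise level for a target signal-to-noise ratio
#'
#' SNR here is the squared membrane-to-solvent contrast over the noise
#' variance: `snr = (solvent - membrane)^2 / sigma^2`.
#'
#' @param contrast absolute membrane-solvent intensity difference.
#' @param snr target signal-to-noise ratio (> 0).
#' @return the Gaussian noise standard deviation giving that SNR.
#' @export
noise_sigma_for_snr <- function(contrast, snr) {
  if (snr <= 0) stopf("`snr` must be > 0")
  abs(contrast) / sqrt(snr)
}

# ---------------------------------------------------------------------------
# Geometry kernels (vectorized signed distances over coordinate arrays)

sdf_box3 <- function(u, v, w, half) {
  qu <- abs(u) - half[1]; qv <- abs(v) - half[2]; qw <- abs(w) - half[3]
  outer_d <- sqrt(pmax(qu, 0)^2 + pmax(qv, 0)^2 + pmax(qw, 0)^2)
  inner_d <- pmin(pmax(qu, pmax(qv, qw)), 0)
  outer_d + inner_d
}

sdf_capped_cylinder <- function(u, v, w, radius, half_len) {
  dr <- sqrt(v^2 + w^2) - radius
  du <- abs(u) - half_len
  sqrt(pmax(dr, 0)^2 + pmax(du, 0)^2) + pmin(pmax(dr, du), 0)
}

## Frame for a crista: columns e1 (length axis), e2 (depth axis), e3.
crista_frame <- function(cs) {
  o <- cs$orientation
  pick_perp <- function(v) {
    ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    unit(pracma_cross(ref, v))
  }
  if (cs$shape %in% c("lamellar", "straight_across", "split")) {
    w <- o                                     # sheet normal
    e1 <- cs$direction %||% pick_perp(w)
    e1 <- unit(e1 - sum(e1 * w) * w)
    e2 <- pracma_cross(w, e1)
    cbind(e1, e2, w)
  } else if (cs$shape == "tubular") {
    e1 <- o                                    # cylinder axis
    e2 <- cs$direction %||% pick_perp(e1)
    e2 <- unit(e2 - sum(e2 * e1) * e1)
    cbind(e1, e2, pracma_cross(e1, e2))
  } else if (cs$shape %in% c("ring", "loop")) {
    ax <- o                                    # torus / extrusion axis
    e1 <- cs$direction %||% pick_perp(ax)
    e1 <- unit(e1 - sum(e1 * ax) * ax)
    cbind(e1, ax, pracma_cross(e1, ax))        # columns: in-plane, axis, in-plane-perp
  } else {                                     # globular
    diag(3)
  }
}

## Signed distance from every voxel to the crista core solid (the region
## bounded by the two membrane midsurfaces); membrane band is |d| <= t/2.
crista_core_sdf <- function(cs, coords) {
  Fm <- crista_frame(cs)
  cx <- coords$x - cs$center_nm[1]
  cy <- coords$y - cs$center_nm[2]
  cz <- coords$z - cs$center_nm[3]
  u <- Fm[1, 1] * cx + Fm[2, 1] * cy + Fm[3, 1] * cz
  v <- Fm[1, 2] * cx + Fm[2, 2] * cy + Fm[3, 2] * cz
  w <- Fm[1, 3] * cx + Fm[2, 3] * cy + Fm[3, 3] * cz
  W <- cs$width_nm; L <- cs$length_nm; D <- cs$depth_nm
  if (cs$shape %in% c("lamellar", "straight_across")) {
    sdf_box3(u, v, w, c(L / 2, D / 2, W / 2))
  } else if (cs$shape == "tubular") {
    sdf_capped_cylinder(u, v, w, W / 2, L / 2)
  } else if (cs$shape == "globular") {
    sqrt(cx^2 + cy^2 + cz^2) - W / 2
  } else if (cs$shape == "ring") {
    R <- L / (2 * pi)
    sqrt((sqrt(u^2 + w^2) - R)^2 + v^2) - W / 2
  } else if (cs$shape == "loop") {
    ext <- cs$arc_deg * pi / 180
    R <- L / ext
    rho <- sqrt(u^2 + w^2)
    th <- atan2(w, u)
    d2 <- abs(rho - R) - W / 2
    outside <- abs(th) > ext / 2
    if (any(outside)) {
      e1p <- R * cos(ext / 2); e2p <- R * sin(ext / 2)
      dA <- sqrt((u - e1p)^2 + (w - e2p)^2) - W / 2
      dB <- sqrt((u - e1p)^2 + (w + e2p)^2) - W / 2
      d2[outside] <- pmin(dA, dB)[outside]
    }
    dv <- abs(v) - D / 2
    sqrt(pmax(d2, 0)^2 + pmax(dv, 0)^2) + pmin(pmax(d2, dv), 0)
  } else { # split: main slab plus a branch slab rotated about the depth axis
    d_main <- sdf_box3(u, v, w, c(L / 2, D / 2, W / 2))
    a <- cs$branch_angle_deg * pi / 180
    bl <- cs$branch_length_nm
    # branch length axis in the (u, w) plane, offset so it grows from the midline
    ub <- cos(a) * u + sin(a) * w - bl / 2
    wb <- -sin(a) * u + cos(a) * w
    d_br <- sdf_box3(ub, v, wb, c(bl / 2, D / 2, W / 2))
    pmin(d_main, d_br)
  }
}

## Half-diagonal reach of the crista (bounding-sphere radius incl. membrane).
crista_reach <- function(cs) {
  t <- 0   # membrane added by caller
  W <- cs$width_nm; L <- cs$length_nm; D <- cs$depth_nm
  switch(cs$shape,
    lamellar = ,
    straight_across = sqrt((L / 2)^2 + (D / 2)^2 + (W / 2)^2),
    tubular = sqrt((L / 2)^2 + (W / 2)^2),
    globular = W / 2,
    ring = L / (2 * pi) + W / 2,
    loop = L / (cs$arc_deg * pi / 180) + W / 2 + D / 2,
    split = sqrt((max(L, cs$branch_length_nm * 2) / 2)^2 + (D / 2)^2) + W / 2
  )
}

## Normalized signed distance (nm) to the OMM midsurface ellipsoid,
## negative inside.  Exact for spheres, first-order exact near the surface
## for general ellipsoids.
ellipsoid_sdf <- function(x, y, z, center, semi) {
  cx <- x - center[1]; cy <- y - center[2]; cz <- z - center[3]
  f <- sqrt(cx^2 / semi[1]^2 + cy^2 / semi[2]^2 + cz^2 / semi[3]^2)
  g <- sqrt(cx^2 / semi[1]^4 + cy^2 / semi[2]^4 + cz^2 / semi[3]^4)
  d <- (f - 1) * f / pmax(g, .Machine$double.eps)
  d[f == 0] <- -min(semi)
  d
}

ellipsoid_volume <- function(semi, inset = 0) {
  s <- semi - inset
  if (any(s <= 0)) return(0)
  4 / 3 * pi * prod(s)
}

## Closed-form displaced volumes (nm^3) of a crista: lumen and total
## (lumen + membrane shell).  Approximate for loop and split (flagged).
crista_volumes <- function(cs, t) {
  W <- cs$width_nm; L <- cs$length_nm; D <- cs$depth_nm
  box_v <- function(l, d, w) max(l, 0) * max(d, 0) * max(w, 0)
  out <- switch(cs$shape,
    lamellar = ,
    straight_across = list(
      lumen = box_v(L - t, D - t, W - t),
      total = box_v(L + t, D + t, W + t), exact = TRUE),
    tubular = list(
      lumen = pi * max(W / 2 - t / 2, 0)^2 * max(L - t, 0),
      total = pi * (W / 2 + t / 2)^2 * (L + t), exact = TRUE),
    globular = list(
      lumen = 4 / 3 * pi * max(W / 2 - t / 2, 0)^3,
      total = 4 / 3 * pi * (W / 2 + t / 2)^3, exact = TRUE),
    ring = {
      R <- L / (2 * pi)
      list(lumen = 2 * pi^2 * R * max(W / 2 - t / 2, 0)^2,
           total = 2 * pi^2 * R * (W / 2 + t / 2)^2, exact = TRUE)
    },
    loop = list(  # arc length x lumen gap x depth, end caps ignored
      lumen = L * max(W - t, 0) * max(D - t, 0),
      total = (L + t) * (W + t) * (D + t), exact = FALSE),
    split = list(
      lumen = box_v(L - t, D - t, W - t) + box_v(cs$branch_length_nm - t, D - t, W - t),
      total = box_v(L + t, D + t, W + t) + box_v(cs$branch_length_nm + t, D + t, W + t),
      exact = FALSE)
  )
  out
}

# ---------------------------------------------------------------------------

#' Generate a phantom tomogram with ground truth
#'
#' Renders the phantom geometry into a density volume (membranes dark, one
#' voxel of analytic anti-aliasing at interfaces), a voxel label volume, and a
#' ground-truth record.  Additive Gaussian noise is applied after rendering
#' and the missing wedge last, mirroring the corruption order of real
#' tomographic reconstruction.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom` with elements `tomogram` ([tomogram()]),
#'   `labels` (a `label_volume`), and `truth` (a `ground_truth` record with
#'   per-crista widths/lengths/classes, per-junction widths/angles, and
#'   closed-form compartment volumes in cubic micrometres).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  t <- spec$membrane_thickness_nm
  g <- spec$ibm_gap_nm
  vox <- spec$voxel_size_nm
  dimv <- spec$box_shape
  ibm_inner <- t / 2 + g + t      # inward offset of the IBM inner face

  # geometry validation: cristae with no junctions must fit inside the IBM;
  # any crista must stay inside the OMM inner surface
  dist_center <- function(cs) {
    -ellipsoid_sdf(cs$center_nm[1], cs$center_nm[2], cs$center_nm[3],
                   spec$center_nm, spec$omm_semi_axes_nm)
  }
  for (i in seq_along(spec$cristae)) {
    cs <- spec$cristae[[i]]
    reach <- crista_reach(cs) + t
    inside <- dist_center(cs)
    if (length(cs$junctions) == 0L && inside - reach < ibm_inner)
      stopf("crista %d (%s) exceeds the IBM interior", i, cs$shape)
    if (inside - ifelse(cs$shape %in% c("straight_across", "loop"), 0, reach) < t / 2)
      stopf("crista %d (%s) breaches the outer membrane", i, cs$shape)
  }

  co <- coord_arrays(dimv, vox)
  d_omm <- ellipsoid_sdf(co$x, co$y, co$z, spec$center_nm, spec$omm_semi_axes_nm)

  # labels from the radial bands
  lab <- array(LABELS[["background"]], dimv)
  lab[d_omm < -ibm_inner] <- LABELS[["matrix"]]
  lab[d_omm >= -ibm_inner & d_omm < -(t / 2 + g)] <- LABELS[["ibm"]]
  lab[d_omm >= -(t / 2 + g) & d_omm < -t / 2] <- LABELS[["ims"]]
  lab[abs(d_omm) <= t / 2] <- LABELS[["omm"]]

  # membrane coverage for the density render (1-voxel linear anti-aliasing)
  aa <- function(dist_mid) pmin(pmax(0.5 + (t / 2 - abs(dist_mid)) / vox, 0), 1)
  cov <- aa(d_omm)
  cov_ibm <- aa(d_omm + (t / 2 + g + t / 2))

  crista_id <- array(0L, dimv)
  lumen_cov_tot <- NULL
  inside_fac <- pmin(pmax((-d_omm - t / 2) / vox + 0.5, 0), 1)
  for (i in seq_along(spec$cristae)) {
    cs <- spec$cristae[[i]]
    d_core <- crista_core_sdf(cs, co)
    mem <- abs(d_core) <= t / 2 & d_omm < -t / 2
    lum <- d_core < -t / 2 & d_omm < -t / 2
    if (!any(mem)) stopf("crista %d (%s) renders no membrane voxels", i, cs$shape)
    lab[mem] <- LABELS[["crista_membrane"]]
    lab[lum] <- LABELS[["cristae_lumen"]]
    crista_id[mem | lum] <- i
    cov_crista <- aa(d_core) * inside_fac
    cov <- pmax(cov, cov_crista)
    lc <- pmin(pmax(0.5 - (d_core + t / 2) / vox, 0), 1)
    lumen_cov_tot <- if (is.null(lumen_cov_tot)) lc else pmax(lumen_cov_tot, lc)
    rm(d_core, mem, lum, cov_crista, lc)
  }
  if (!is.null(lumen_cov_tot)) cov_ibm <- cov_ibm * (1 - lumen_cov_tot)
  cov <- pmax(cov, cov_ibm)
  dens <- spec$solvent_density + (spec$membrane_density - spec$solvent_density) * cov
  rm(cov, cov_ibm, lumen_cov_tot, inside_fac, co)

  if (spec$smooth_sigma_vox > 0)
    dens <- gaussian_smooth3(dens, spec$smooth_sigma_vox)

  if (spec$noise_sigma > 0) {
    dens <- dens + with_seed(spec$seed,
      array(stats::rnorm(prod(dimv), sd = spec$noise_sigma), dimv))
  }

  tomo <- tomogram(dens, vox, meta = list(phantom_seed = spec$seed))
  if (spec$wedge_half_angle_deg > 0)
    tomo <- apply_missing_wedge(tomo, spec$wedge_half_angle_deg)

  labels <- structure(list(data = lab, voxel_size_nm = vox, map = LABELS,
                           crista_id = crista_id),
                      class = "label_volume")

  truth <- build_ground_truth(spec)
  structure(list(tomogram = tomo, labels = labels, truth = truth, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>\n")
  print(x$tomogram)
  cat(sprintf("  %d crista(e); compartments (um^3): matrix %.4g, IMS %.4g, CL %.4g\n",
              nrow(x$truth$cristae), x$truth$volumes$matrix_um3,
              x$truth$volumes$ims_um3, x$truth$volumes$cl_um3))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %.4g nm\n", d[1], d[2], d[3],
              x$voxel_size_nm))
  tb <- table(factor(x$data, levels = x$map, labels = names(x$map)))
  print(tb)
  invisible(x)
}

build_ground_truth <- function(spec) {
  t <- spec$membrane_thickness_nm
  g <- spec$ibm_gap_nm
  a <- spec$omm_semi_axes_nm
  nm3_to_um3 <- 1e-9

  v_omm_inner <- ellipsoid_volume(a, t / 2)
  v_ibm_outer <- ellipsoid_volume(a, t / 2 + g)
  v_matrix_region <- ellipsoid_volume(a, t / 2 + g + t)
  ims <- v_omm_inner - v_ibm_outer

  cl <- 0; crista_total <- 0; exact <- TRUE
  cr_rows <- list(); j_rows <- list()
  jid <- 0L
  for (i in seq_along(spec$cristae)) {
    cs <- spec$cristae[[i]]
    cv <- crista_volumes(cs, t)
    cl <- cl + cv$lumen
    crista_total <- crista_total + cv$total
    exact <- exact && cv$exact && length(cs$junctions) == 0L
    cr_rows[[i]] <- data.frame(
      crista_id = i, shape = cs$shape, width_nm = cs$width_nm,
      length_nm = cs$length_nm, n_junctions = length(cs$junctions),
      stringsAsFactors = FALSE)
    for (j in cs$junctions) {
      jid <- jid + 1L
      j_rows[[jid]] <- data.frame(
        junction_id = jid, crista_id = i,
        width_nm = j$width_nm %||% NA_real_,
        angle_deg = j$angle_deg %||% 90)
    }
  }
  matrix_v <- v_matrix_region - crista_total

  truth <- list(
    cristae = if (length(cr_rows)) do.call(rbind, cr_rows) else
      data.frame(crista_id = integer(), shape = character(), width_nm = numeric(),
                 length_nm = numeric(), n_junctions = integer()),
    junctions = if (length(j_rows)) do.call(rbind, j_rows) else
      data.frame(junction_id = integer(), crista_id = integer(),
                 width_nm = numeric(), angle_deg = numeric()),
    volumes = list(matrix_um3 = matrix_v * nm3_to_um3,
                   ims_um3 = ims * nm3_to_um3,
                   cl_um3 = cl * nm3_to_um3,
                   total_um3 = (matrix_v + ims + cl) * nm3_to_um3,
                   exact = exact),
    spec = spec
  )
  class(truth) <- "ground_truth"
  truth
}

# separable Gaussian smoothing via FFT (circular)
gaussian_smooth3 <- function(x, sigma) {
  d <- dim(x)
  k1 <- function(n) {
    i <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-i^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(stats::fft(k1(d[1])), stats::fft(k1(d[2]))), stats::fft(k1(d[3])))
  Re(stats::fft(stats::fft(x) * array(K, d), inverse = TRUE)) / prod(d)
}

# ---------------------------------------------------------------------------
# Missing wedge

#' Logical mask of missing-wedge Fourier components
#'
#' The wedge sits about the beam (z) axis and is invariant along the tilt (y)
#' axis: component `(kx, ky, kz)` is missing when the angle between the
#' `(kx, kz)` projection and the `kz` axis is less than the half angle.  The
#' DC component is always kept.
#'
#' @param dim volume dimensions.
#' @param half_angle_deg wedge half angle in degrees.
#' @return a logical array, `TRUE` where components are removed.
#' @export
missing_wedge_mask <- function(dim, half_angle_deg) {
  th <- half_angle_deg * pi / 180
  fx <- fft_freq(dim[1]); fz <- fft_freq(dim[3])
  m2 <- outer(fx, fz, function(a, b) (a != 0 | b != 0) & atan2(abs(a), abs(b)) < th)
  aperm(array(m2, c(dim[1], dim[3], dim[2])), c(1, 3, 2))
}

#' Apply a missing wedge in Fourier space
#'
#' Zeroes the Fourier components inside the wedge (see
#' [missing_wedge_mask()]); the operation is an idempotent projection and
#' returns a real-valued volume.  A tilt range of +/-70 degrees corresponds to
#' a 20 degree half angle.
#'
#' @param tomo a [tomogram()].
#' @param wedge_half_angle_deg half angle in `[0, 90]`.
#' @return the filtered [tomogram()].
#' @export
apply_missing_wedge <- function(tomo, wedge_half_angle_deg) {
  stopifnot(inherits(tomo, "tomogram"))
  if (wedge_half_angle_deg < 0 || wedge_half_angle_deg > 90)
    stopf("`wedge_half_angle_deg` must be in [0, 90]")
  if (wedge_half_angle_deg == 0) return(tomo)
  d <- dim(tomo$data)
  Fv <- stats::fft(tomo$data)
  Fv[missing_wedge_mask(d, wedge_half_angle_deg)] <- 0
  tomo$data <- Re(stats::fft(Fv, inverse = TRUE)) / prod(d)
  tomo$meta$wedge_half_angle_deg <- wedge_half_angle_deg
  tomo
}

# ---------------------------------------------------------------------------
# Particle sampling

#' Sample particle positions on crista midplanes
#'
#' Draws `n` positions on the lumen midplanes of sheet-like cristae (lamellar
#' or straight-across), recording the local membrane normal for each.  The
#' draw is deterministic under a fixed seed.
#'
#' @param labels the phantom `label_volume`.
#' @param ground the phantom `ground_truth`.
#' @param n number of positions; `0` returns an empty set.
#' @param seed integer seed.
#' @param spacing_vox candidate-site spacing on the midplane (voxels).
#' @param margin_nm margin kept from the crista rim.
#' @return a data.frame with fractional voxel coordinates `x, y, z`, the unit
#'   membrane normal `nx, ny, nz`, and `crista_id`.
#' @export
sample_particles <- function(labels, ground, n, seed = 1L, spacing_vox = 1,
                             margin_nm = NULL) {
  stopifnot(inherits(labels, "label_volume"), inherits(ground, "ground_truth"))
  spec <- ground$spec
  if (length(spec$cristae) == 0L) stopf("phantom contains no cristae")
  vox <- labels$voxel_size_nm
  if (is.null(margin_nm)) margin_nm <- spec$membrane_thickness_nm + 2 * vox
  sites <- list()
  for (i in seq_along(spec$cristae)) {
    cs <- spec$cristae[[i]]
    if (!cs$shape %in% c("lamellar", "straight_across")) next
    Fm <- crista_frame(cs)
    hu <- cs$length_nm / 2 - margin_nm
    hv <- cs$depth_nm / 2 - margin_nm
    if (hu <= 0 || hv <= 0) next
    us <- seq(-hu, hu, by = spacing_vox * vox)
    vs <- seq(-hv, hv, by = spacing_vox * vox)
    gsites <- expand.grid(u = us, v = vs)
    p <- cbind(cs$center_nm[1] + gsites$u * Fm[1, 1] + gsites$v * Fm[1, 2],
               cs$center_nm[2] + gsites$u * Fm[2, 1] + gsites$v * Fm[2, 2],
               cs$center_nm[3] + gsites$u * Fm[3, 1] + gsites$v * Fm[3, 2])
    dimnames(p) <- NULL
    sites[[length(sites) + 1L]] <- data.frame(
      x = p[, 1] / vox + 0.5, y = p[, 2] / vox + 0.5, z = p[, 3] / vox + 0.5,
      nx = rep(unname(Fm[1, 3]), nrow(p)), ny = rep(unname(Fm[2, 3]), nrow(p)),
      nz = rep(unname(Fm[3, 3]), nrow(p)), crista_id = i)
  }
  if (length(sites) == 0L)
    stopf("no sheet-like cristae available for particle sampling")
  pool <- do.call(rbind, sites)
  if (n == 0L) return(pool[0, , drop = FALSE])
  if (n > nrow(pool))
    stopf("requested %d particles but only %d distinct sites available", n, nrow(pool))
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
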