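# 3D morphometrics on label volumes: compartment volumes, crista centerlines
# and length, rule-based cristae shape taxonomy, stacking and multijunction
# classes, and 2D mitochondrion shape.
#
# Thresholds live in shape_control(); the defaults are chosen so canonical
# geometric exemplars classify unambiguously (the study itself classified by
# visual inspection, so the cutoffs are explicit package parameters, not
# inferred values).

#' Classification thresholds
#'
#' @param lamellar_ratio two principal extents must each exceed this multiple
#'   of the third for a lamellar call (default 3).
#' @param tubular_ratio leading extent over second for a tubular call
#'   (default 3).
#' @param tubular_round_max maximum second/third extent ratio for tubular
#'   (default 1.5).
#' @param globular_max maximum max/min extent ratio for globular (default 2).
#' @param loop_straightness_max end-to-end over arc-length below which a
#'   two-junction crista is a loop (default 0.8).
#' @param straight_min straightness at or above which a two-junction crista is
#'   straight-across (default 0.95).
#' @param zip_min_len_nm minimum length of a collapsed-lumen stretch to call
#'   zipped rather than pinched (default 20 nm).
#' @param lumen_floor_nm resolvable lumen-width floor, one template step
#'   (default 2.2 nm).
#' @param vesicular_contrast_max lumen density contrast (1 = solvent-like,
#'   0 = membrane-like) below which a crista is vesicular (default 0.6).
#' @param parallel_tol_deg pairwise sheet-normal tolerance for stacking
#'   (default 15 degrees).
#' @param overlap_min minimum mutual footprint overlap for stacking
#'   (default 0.5).
#' @param tilt_tolerance_deg junction-angle tolerance around 90 degrees for a
#'   "straight" directionality call (default 20).
#' @param aspect_min fitted-ellipse aspect ratio separating round from
#'   ellipsoidal mitochondria (default 1.3).
#' @param solidity_min solidity below which a mitochondrion outline is
#'   "polygon" (default 0.95).
#' @param spur_prune_px skeleton spur-pruning depth in pixels (default 4).
#' @return a named list of thresholds.
#' @export
shape_control <- function(lamellar_ratio = 3, tubular_ratio = 3,
                          tubular_round_max = 1.5, globular_max = 2,
                          loop_straightness_max = 0.8, straight_min = 0.95,
                          zip_min_len_nm = 20, lumen_floor_nm = 2.2,
                          vesicular_contrast_max = 0.6,
                          parallel_tol_deg = 15, overlap_min = 0.5,
                          tilt_tolerance_deg = 20,
                          aspect_min = 1.3, solidity_min = 0.95,
                          spur_prune_px = 4L) {
  as.list(environment())
}

# ---------------------------------------------------------------------------
# Compartment volumes

#' Compartment volumes from a label volume
#'
#' Volumes are voxel counts times the voxel volume; the total is the exact sum
#' of matrix, intermembrane space (IMS) and cristae lumen (CL).
#'
#' @param labels a `label_volume` (e.g. from [generate_phantom()]).
#' @return an object of class `volume_report` with `matrix_um3`, `ims_um3`,
#'   `cl_um3`, `total_um3` and the CL/IMS/matrix fractions of the total
#'   (`NA` when the total is zero).
#' @export
compartment_volumes <- function(labels) {
  if (!inherits(labels, "label_volume"))
    stopf("`labels` must be a label_volume")
  need <- c("matrix", "ims", "cristae_lumen")
  missing <- setdiff(need, names(labels$map))
  if (length(missing))
    stopf("label map lacks compartment classes: %s", paste(missing, collapse = ", "))
  vv <- labels$voxel_size_nm^3 * 1e-9   # nm^3 -> um^3
  cnt <- function(cls) sum(labels$data == labels$map[[cls]]) * vv
  m <- cnt("matrix"); i <- cnt("ims"); c_ <- cnt("cristae_lumen")
  tot <- m + i + c_
  ratios <- if (tot > 0) list(cl = c_ / tot, ims = i / tot, matrix = m / tot)
            else list(cl = NA_real_, ims = NA_real_, matrix = NA_real_)
  structure(list(matrix_um3 = m, ims_um3 = i, cl_um3 = c_, total_um3 = tot,
                 ratios = ratios), class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> total %.5g um^3 = matrix %.5g + IMS %.5g + CL %.5g\n",
              x$total_um3, x$matrix_um3, x$ims_um3, x$cl_um3))
  if (!is.na(x$ratios$cl))
    cat(sprintf("  fractions: CL %.3f, IMS %.3f, matrix %.3f\n",
                x$ratios$cl, x$ratios$ims, x$ratios$matrix))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Crista components

#' Extract per-crista components from a label volume
#'
#' Uses the generator's crista index map when present, otherwise 26-connected
#' components over crista-membrane and cristae-lumen voxels.
#'
#' @param labels a `label_volume`.
#' @return a list of components, each a list with integer voxel coordinates
#'   `coords` (n x 3), a logical `lumen` marker per voxel, `crista_id` and
#'   `voxel_size_nm`.
#' @export
crista_components <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$data
  is_cr <- lab == labels$map[["crista_membrane"]] | lab == labels$map[["cristae_lumen"]]
  if (!any(is_cr)) return(list())
  idx <- which(is_cr)
  coords <- arrayInd(idx, dim(lab))
  lumen <- lab[idx] == labels$map[["cristae_lumen"]]
  if (!is.null(labels$crista_id)) {
    ids <- labels$crista_id[idx]
  } else {
    ids <- voxel_components(coords)
  }
  lapply(sort(unique(ids[ids > 0])), function(i) {
    sel <- ids == i
    list(coords = coords[sel, , drop = FALSE], lumen = lumen[sel],
         crista_id = i, voxel_size_nm = labels$voxel_size_nm)
  })
}

## 26-connected component labels for a voxel coordinate list.
voxel_components <- function(coords) {
  key <- function(m) (m[, 3] * 1e5 + m[, 2]) * 1e5 + m[, 1]
  k0 <- key(coords)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
            (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0)))), ,
            drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    kn <- key(sweep(coords, 2, offs[r, ], `+`))
    hit <- match(kn, k0)
    ok <- !is.na(hit)
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(which(ok), hit[ok])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(coords) - igraph::vcount(g)))
  igraph::components(g)$membership
}

# ---------------------------------------------------------------------------
# Centerline and length

#' Length of a 3D polyline
#'
#' @param centerline n x 3 matrix of voxel coordinates (>= 2 points).
#' @param voxel_size_nm voxel edge (nm).
#' @return length in nm (sum of Euclidean segment lengths times voxel size).
#' @export
crista_length <- function(centerline, voxel_size_nm) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L) stopf("a centerline needs at least 2 points")
  if (voxel_size_nm <= 0) stopf("`voxel_size_nm` must be > 0")
  d <- diff(centerline)
  sum(sqrt(rowSums(d^2))) * voxel_size_nm
}

#' Centerline of a crista component
#'
#' Returns the longest geodesic path through the component's voxel adjacency
#' graph (26-connectivity, Euclidean edge weights), lightly smoothed; closed
#' (ring) cristae are detected from the cross-section skeleton and reported
#' with the cycle length instead.
#'
#' @param comp one component from [crista_components()].
#' @param max_voxels components larger than this are strided down before the
#'   geodesic search (default 30000).
#' @return a list with `polyline` (m x 3 voxel coordinates), `length_nm`, and
#'   `is_ring`.
#' @export
skeletonize_crista <- function(comp, max_voxels = 30000L) {
  if (nrow(comp$coords) < 3L) stopf("component smaller than 3 voxels")
  desc <- crista_descriptors(comp)
  if (desc$has_cycle && !is.null(desc$cycle_polyline3d)) {
    return(list(polyline = desc$cycle_polyline3d, length_nm = desc$cycle_len_nm,
                is_ring = TRUE))
  }
  coords <- comp$coords
  stride <- 1L
  if (nrow(coords) > max_voxels) {
    stride <- ceiling((nrow(coords) / max_voxels)^(1 / 3))
    coords <- unique(floor((coords - 1L) / stride)) + 1L
  }
  g <- voxel_graph(coords)
  d0 <- igraph::distances(g, v = 1)
  a <- which.max(d0)
  da <- igraph::distances(g, v = a)
  b <- which.max(da)
  path <- as.integer(igraph::shortest_paths(g, from = a, to = b)$vpath[[1]])
  pl <- coords[path, , drop = FALSE] * stride
  pl <- smooth_polyline(pl, window = 5L)
  list(polyline = pl,
       length_nm = crista_length(pl, comp$voxel_size_nm),
       is_ring = FALSE)
}

voxel_graph <- function(coords) {
  key <- function(m) (m[, 3] * 1e5 + m[, 2]) * 1e5 + m[, 1]
  k0 <- key(coords)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
            (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0)))), ,
            drop = FALSE]
  el <- list(); wt <- list()
  for (r in seq_len(nrow(offs))) {
    kn <- key(sweep(coords, 2, offs[r, ], `+`))
    hit <- match(kn, k0)
    ok <- !is.na(hit)
    if (any(ok)) {
      el[[length(el) + 1L]] <- cbind(which(ok), hit[ok])
      wt[[length(wt) + 1L]] <- rep(sqrt(sum(offs[r, ]^2)), sum(ok))
    }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(coords) - igraph::vcount(g)))
  igraph::E(g)$weight <- unlist(wt)
  g
}

smooth_polyline <- function(p, window = 5L) {
  n <- nrow(p)
  if (n <= window) return(p)
  h <- window %/% 2L
  out <- p
  for (i in seq_len(n)) {
    r <- max(1, i - h):min(n, i + h)
    out[i, ] <- colMeans(p[r, , drop = FALSE])
  }
  out
}

# ---------------------------------------------------------------------------
# Cross-section descriptors

## Project a crista component to 2D cross-sections and derive the topology /
## straightness / lumen descriptors that drive the shape cascade.  Two
## projections are used: the one along the smallest-extent principal axis
## detects closed (ring) topology as an enclosed 2D hole, while the
## minimum-area projection over all three axes yields the curve skeleton for
## straightness, branching and the lumen width profile.
crista_descriptors <- function(comp, control = shape_control()) {
  vox <- comp$voxel_size_nm
  coords <- comp$coords
  ctr <- colMeans(coords)
  pc <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  sc <- pc$x
  extents_raw <- apply(sc, 2, function(v) diff(range(v)))
  extents_nm <- (extents_raw + 1) * vox
  ord <- order(extents_nm, decreasing = TRUE)
  extents_nm <- extents_nm[ord]
  normal <- pc$rotation[, ord[3]]          # smallest-variation axis

  # footprints are binned at 2-voxel cells: solid components populate every
  # cell, so the rotated-lattice moire holes of 1-voxel rasterization vanish
  bin <- 2
  footprint <- function(ax) {
    ij <- setdiff(1:3, ax)
    f2 <- floor(sc[, ij, drop = FALSE] / bin)
    off <- apply(f2, 2, min) - 3L
    f2 <- sweep(f2, 2, off)
    dims <- apply(f2, 2, max) + 3L
    mask <- matrix(FALSE, dims[1], dims[2])
    mask[f2] <- TRUE
    list(mask = mask, cells = f2, ij = ij, off = off, count = sum(mask))
  }
  fps <- lapply(1:3, footprint)

  # ring topology: enclosed hole in the projection along the thinnest axis
  fmin <- fps[[ord[3]]]
  has_cycle <- footprint_has_hole(fmin$mask)
  cycle_polyline3d <- NULL; cycle_len_nm <- NA_real_
  if (has_cycle) {
    stc <- skeleton_stats(thin2d(fmin$mask), control$spur_prune_px)
    if (!is.null(stc$cycle)) {
      p2 <- (stc$cycle + matrix(fmin$off, nrow(stc$cycle), 2, byrow = TRUE)) * bin
      back <- matrix(0, nrow(p2), 3)
      back[, fmin$ij[1]] <- p2[, 1]
      back[, fmin$ij[2]] <- p2[, 2]
      pl3 <- back %*% t(pc$rotation)
      cycle_polyline3d <- sweep(pl3, 2, ctr, `+`)
      cycle_len_nm <- stc$cycle_len * vox * bin
    }
  }

  # curve skeleton from the minimum-area projection
  ax <- which.min(vapply(fps, `[[`, numeric(1), "count"))
  fp <- fps[[ax]]
  lmask <- matrix(FALSE, nrow(fp$mask), ncol(fp$mask))
  if (any(comp$lumen)) lmask[fp$cells[comp$lumen, , drop = FALSE]] <- TRUE
  st <- skeleton_stats(thin2d(fp$mask), control$spur_prune_px)

  straightness <- NA_real_
  path2d <- NULL
  if (!is.null(st$path)) {
    path2d <- st$path
    ee <- sqrt(sum((path2d[1, ] - path2d[nrow(path2d), ])^2))
    straightness <- if (st$path_len > 0) ee / st$path_len else NA_real_
  }
  lumen_profile <- NULL
  if (!is.null(path2d) && nrow(path2d) >= 3L) {
    lumen_profile <- lumen_width_profile(path2d, lmask, vox * bin)
  }

  list(extents_nm = extents_nm, normal = normal,
       n_endpoints = st$n_endpoints, n_branchpoints = st$n_branchpoints,
       has_cycle = has_cycle, straightness = straightness,
       lumen_profile = lumen_profile, profile_step_nm = vox * bin,
       cycle_polyline3d = cycle_polyline3d, cycle_len_nm = cycle_len_nm,
       footprint_cells = fp$cells)
}

## TRUE when the 2D footprint encloses background (flood fill from the
## border leaves an unreached background region of at least `min_hole` px).
footprint_has_hole <- function(mask, min_hole = 4L) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(bg), ncol(bg))
  reach[1, ] <- bg[1, ]; reach[nrow(bg), ] <- bg[nrow(bg), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(bg)] <- bg[, ncol(bg)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(reach), ] <- grown[-nrow(reach), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(reach)] <- grown[, -ncol(reach)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  sum(bg & !reach) >= min_hole
}

## Zhang-Suen thinning of a logical matrix to a 1-pixel curve skeleton.
thin2d <- function(mask) {
  m <- mask
  shift2 <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p2 <- shift2(m, 1, 0);  p3 <- shift2(m, 1, -1)
      p4 <- shift2(m, 0, -1); p5 <- shift2(m, -1, -1)
      p6 <- shift2(m, -1, 0); p7 <- shift2(m, -1, 1)
      p8 <- shift2(m, 0, 1);  p9 <- shift2(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 0) {
        cond <- m & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

## Remove spur chains: endpoint chains of at most `depth` pixels that
## terminate at a branch point are thinning artifacts, not real structure.
prune_spurs <- function(g, depth) {
  repeat {
    deg <- igraph::degree(g)
    ends <- which(deg == 1L)
    if (!length(ends) || depth < 1L) return(g)
    to_drop <- integer()
    for (e in ends) {
      chain <- e; cur <- e; prev <- -1L
      repeat {
        nbr <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nbr) != 1L) { chain <- integer(); break }  # isolated / end
        if (deg[nbr] >= 3L) break                              # spur confirmed
        if (length(chain) >= depth) { chain <- integer(); break }
        prev <- cur; cur <- nbr; chain <- c(chain, cur)
      }
      to_drop <- c(to_drop, chain)
    }
    to_drop <- unique(to_drop)
    if (!length(to_drop)) return(g)
    g <- igraph::delete_vertices(g, to_drop)
  }
}

## Topology and main-path statistics of a 2D skeleton.
skeleton_stats <- function(skel, prune_depth = 4L) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 2L)
    return(list(n_endpoints = 0L, n_branchpoints = 0L, has_cycle = FALSE,
                path = NULL, path_len = 0, cycle = NULL, cycle_len = 0))
  key <- px[, 1] * 1e5 + px[, 2]
  el <- list(); wt <- list()
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (r in seq_len(nrow(offs))) {
    kn <- (px[, 1] + offs[r, 1]) * 1e5 + (px[, 2] + offs[r, 2])
    hit <- match(kn, key)
    ok <- !is.na(hit)
    if (all(offs[r, ] != 0)) {
      # a diagonal edge is redundant when the two pixels already share an
      # orthogonal skeleton neighbor (avoids spurious staircase cycles)
      k1 <- (px[, 1] + offs[r, 1]) * 1e5 + px[, 2]
      k2 <- px[, 1] * 1e5 + (px[, 2] + offs[r, 2])
      ok <- ok & is.na(match(k1, key)) & is.na(match(k2, key))
    }
    if (any(ok)) {
      el[[length(el) + 1L]] <- cbind(which(ok), hit[ok])
      wt[[length(wt) + 1L]] <- rep(sqrt(sum(offs[r, ]^2)), sum(ok))
    }
  }
  if (!length(el))
    return(list(n_endpoints = n, n_branchpoints = 0L, has_cycle = FALSE,
                path = NULL, path_len = 0, cycle = NULL, cycle_len = 0))
  g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- unlist(wt)
  igraph::V(g)$px_row <- seq_len(igraph::vcount(g))
  g <- prune_spurs(g, prune_depth)
  px <- px[igraph::V(g)$px_row, , drop = FALSE]
  n <- nrow(px)
  deg <- igraph::degree(g)
  ends <- which(deg == 1L)
  branches <- which(deg >= 3L)
  comp <- igraph::components(g)
  has_cycle <- igraph::ecount(g) - igraph::vcount(g) + comp$no >= 1L

  path <- NULL; path_len <- 0
  if (length(ends) >= 2L) {
    dm <- igraph::distances(g, v = ends, to = ends)
    w <- which(dm == max(dm[is.finite(dm)]), arr.ind = TRUE)[1, ]
    sp <- igraph::shortest_paths(g, from = ends[w[1]], to = ends[w[2]])
    vp <- as.integer(sp$vpath[[1]])
    path <- px[vp, , drop = FALSE]
    path_len <- dm[w[1], w[2]]
  }
  cycle <- NULL; cycle_len <- 0
  if (has_cycle && length(ends) == 0L) {
    # pure cycle: circumference ~ twice the maximal pairwise geodesic
    main <- which(comp$membership == which.max(comp$csize))
    cycle <- px[main, , drop = FALSE]
    d0 <- igraph::distances(g, v = main[1], to = main)
    a <- main[which.max(d0)]
    da <- igraph::distances(g, v = a, to = main)
    cycle_len <- 2 * max(da[is.finite(da)])
  }
  list(n_endpoints = length(ends), n_branchpoints = length(branches),
       has_cycle = has_cycle, path = path, path_len = path_len,
       cycle = cycle, cycle_len = cycle_len)
}

## Lumen width (nm) sampled along a skeleton path: at each path pixel, the
## contiguous lumen run through the point measured perpendicular to the path.
lumen_width_profile <- function(path, lmask, vox, max_scan_px = 30) {
  n <- nrow(path)
  widths <- numeric(n)
  look <- function(r, c_) {
    ri <- round(r); ci <- round(c_)
    ri >= 1 & ri <= nrow(lmask) & ci >= 1 & ci <= ncol(lmask) &
      lmask[cbind(pmax(pmin(ri, nrow(lmask)), 1), pmax(pmin(ci, ncol(lmask)), 1))]
  }
  for (i in seq_len(n)) {
    j0 <- max(1, i - 2); j1 <- min(n, i + 2)
    tg <- path[j1, ] - path[j0, ]
    if (all(tg == 0)) { widths[i] <- 0; next }
    tg <- tg / sqrt(sum(tg^2))
    nr <- c(-tg[2], tg[1])
    # expand outward from the path point while lumen present
    run <- 0
    if (look(path[i, 1], path[i, 2]) ||
        look(path[i, 1] + 0.5 * nr[1], path[i, 2] + 0.5 * nr[2]) ||
        look(path[i, 1] - 0.5 * nr[1], path[i, 2] - 0.5 * nr[2])) {
      for (sgn in c(1, -1)) {
        t_ <- 0.5
        while (t_ <= max_scan_px &&
               look(path[i, 1] + sgn * t_ * nr[1], path[i, 2] + sgn * t_ * nr[2])) {
          t_ <- t_ + 0.5
        }
        run <- run + (t_ - 0.5)
      }
      run <- run + 1   # the central pixel itself
    }
    widths[i] <- run * vox
  }
  widths
}

# ---------------------------------------------------------------------------
# Classification

#' Classify crista directionality
#'
#' A crista with no captured junction is "no attachment observed" (NAO);
#' otherwise it is straight when every junction angle lies within the
#' tolerance of perpendicular (90 degrees), else tilted.
#'
#' @param n_junctions number of cristae junctions captured.
#' @param angles_deg junction angles (degrees, 90 = perpendicular to the IBM).
#' @param tilt_tolerance_deg tolerance around 90 (default 20).
#' @return `"NAO"`, `"straight"` or `"tilted"`.
#' @export
classify_directionality <- function(n_junctions, angles_deg = numeric(),
                                    tilt_tolerance_deg = 20) {
  if (n_junctions == 0L) return("NAO")
  if (length(angles_deg) == 0L)
    stopf("junction angles required when n_junctions > 0")
  if (all(abs(angles_deg - 90) <= tilt_tolerance_deg)) "straight" else "tilted"
}

#' Classify a crista's 3D shape
#'
#' Applies the rule cascade: ring (closed cross-section skeleton, no
#' junctions), loop (two junctions, curved centerline), straight-across (two
#' junctions, near-straight centerline), split (skeleton branch point),
#' zipped (a collapsed-lumen stretch of at least `zip_min_len_nm`), pinched
#' (shorter isolated collapses), vesicular (dense material in the lumen), and
#' finally canonical geometry (lamellar / tubular / globular by principal
#' extents, otherwise amorphous).  Any unusual subclass implies shape class
#' `"unusual"`.
#'
#' @param comp a component from [crista_components()].
#' @param n_junctions number of junctions this crista makes with the IBM
#'   (taken from ground truth or manual picks).
#' @param lumen_contrast optional lumen density contrast from
#'   [crista_lumen_contrast()] (1 = solvent-like, 0 = membrane-like).
#' @param control thresholds from [shape_control()].
#' @return a list with `shape_class` (`lamellar`, `tubular`, `globular` or
#'   `unusual`), `unusual_subclass` (`none` or one of `loop`, `split`,
#'   `straight_across`, `amorphous`, `ring`, `pinched`, `zipped`,
#'   `vesicular`), and the geometric `descriptors`.
#' @export
classify_shape <- function(comp, n_junctions = 0L, lumen_contrast = NA_real_,
                           control = shape_control()) {
  if (nrow(comp$coords) < 4L) stopf("component too small to classify")
  d <- crista_descriptors(comp, control)
  res <- function(cls, sub = "none")
    list(shape_class = cls, unusual_subclass = sub, descriptors = d)

  if (d$has_cycle && n_junctions == 0L) return(res("unusual", "ring"))
  if (n_junctions == 2L && !is.na(d$straightness)) {
    if (d$straightness < control$loop_straightness_max) return(res("unusual", "loop"))
    if (d$straightness >= control$straight_min) return(res("unusual", "straight_across"))
  }
  if (d$n_branchpoints >= 1L) return(res("unusual", "split"))
  if (!is.null(d$lumen_profile) && any(comp$lumen)) {
    runs <- collapsed_runs(d$lumen_profile, d$profile_step_nm,
                           control$lumen_floor_nm)
    if (length(runs)) {
      if (max(runs) >= control$zip_min_len_nm) return(res("unusual", "zipped"))
      return(res("unusual", "pinched"))
    }
  }
  if (!is.na(lumen_contrast) && lumen_contrast < control$vesicular_contrast_max)
    return(res("unusual", "vesicular"))

  e <- d$extents_nm
  if (e[2] >= control$lamellar_ratio * e[3]) return(res("lamellar"))
  if (e[1] >= control$tubular_ratio * e[2] &&
      e[2] / e[3] < control$tubular_round_max) return(res("tubular"))
  if (e[1] / e[3] < control$globular_max) return(res("globular"))
  res("unusual", "amorphous")
}

## Interior stretches (nm) where the lumen width sits below the resolvable
## floor.  Collapsed runs touching either path end are excluded: the membrane
## rim at a crista tip has no lumen by construction and is not a collapse.
collapsed_runs <- function(profile, step_nm, floor_nm) {
  n <- length(profile)
  if (n < 5L) return(numeric())
  r <- rle(profile < floor_nm)
  keep <- r$values
  keep[c(1L, length(keep))] <- FALSE
  r$lengths[keep] * step_nm
}

#' Lumen density contrast of a crista
#'
#' Mean lumen intensity scaled between the component's membrane level (0) and
#' the matrix (solvent) level (1); values well below 1 indicate electron-dense
#' material inside the lumen (the vesicular phenotype).
#'
#' @param comp a component from [crista_components()].
#' @param tomo the [tomogram()] the labels refer to.
#' @param labels the `label_volume`.
#' @return a scalar contrast, or `NA` when the crista has no lumen voxels.
#' @export
crista_lumen_contrast <- function(comp, tomo, labels) {
  if (!any(comp$lumen)) return(NA_real_)
  d <- dim(tomo$data)
  lidx <- comp$coords[comp$lumen, , drop = FALSE]
  midx <- comp$coords[!comp$lumen, , drop = FALSE]
  mu_l <- mean(tomo$data[lidx])
  mu_m <- mean(tomo$data[midx])
  mu_s <- mean(tomo$data[labels$data == labels$map[["matrix"]]])
  if (abs(mu_s - mu_m) < .Machine$double.eps) return(NA_real_)
  (mu_l - mu_m) / (mu_s - mu_m)
}

#' Detect the cristae-stacking phenotype
#'
#' TRUE when at least three lamellar cristae have pairwise sheet-normal angles
#' within the parallel tolerance and mutually overlapping footprints along the
#' common normal.
#'
#' @param cristae list of entries, each with `shape_class`, `normal` (unit
#'   3-vector) and `coords` (n x 3 voxel coordinates); typically built from
#'   [classify_shape()] results.
#' @param control thresholds from [shape_control()].
#' @return logical flag.
#' @export
detect_stacking <- function(cristae, control = shape_control()) {
  lam <- Filter(function(cr) identical(cr$shape_class, "lamellar"), cristae)
  if (length(lam) < 3L) return(FALSE)
  fold <- function(a) min(a, 180 - a)
  foot <- function(cr, nrm) {
    b <- rotation_to_z(nrm)          # columns: in-plane u, v, normal
    p <- cr$coords %*% b[, 1:2]
    unique(paste(round(p[, 1]), round(p[, 2])))
  }
  idx <- utils::combn(length(lam), 3)
  for (c_ in seq_len(ncol(idx))) {
    tri <- lam[idx[, c_]]
    angs <- c(fold(angle_between(tri[[1]]$normal, tri[[2]]$normal)),
              fold(angle_between(tri[[1]]$normal, tri[[3]]$normal)),
              fold(angle_between(tri[[2]]$normal, tri[[3]]$normal)))
    if (any(angs > control$parallel_tol_deg)) next
    nrm <- tri[[1]]$normal
    fps <- lapply(tri, foot, nrm = nrm)
    ov <- function(a, b) length(intersect(a, b)) / min(length(a), length(b))
    if (ov(fps[[1]], fps[[2]]) >= control$overlap_min &&
        ov(fps[[1]], fps[[3]]) >= control$overlap_min &&
        ov(fps[[2]], fps[[3]]) >= control$overlap_min) return(TRUE)
  }
  FALSE
}

#' Classify a multijunction crista as straight or loop
#'
#' @param n_junctions junction count.
#' @param straightness end-to-end over arc-length of the centerline (from
#'   [classify_shape()] descriptors).
#' @param control thresholds from [shape_control()].
#' @return `"none"` (fewer than 2 junctions), `"straight"` or `"loop"`.
#' @export
classify_multijunction <- function(n_junctions, straightness,
                                   control = shape_control()) {
  if (n_junctions < 2L) return("none")
  if (is.na(straightness)) return("loop")
  if (straightness >= control$straight_min) "straight" else "loop"
}

#' Classify a mitochondrion outline
#'
#' Partial when the outline touches the field boundary; otherwise round or
#' ellipsoidal by fitted-ellipse aspect ratio (both requiring high solidity)
#' and "polygon" when the outline is concave or lobed.
#'
#' @param vertices n x 2 matrix of outline vertices (pixel coordinates).
#' @param image_dim image dimensions `(nx, ny)` in pixels.
#' @param control thresholds from [shape_control()].
#' @param border_tol_px distance to the field edge counting as touching
#'   (default 1 pixel).
#' @return `"partial"`, `"round"`, `"ellipsoidal"` or `"polygon"`.
#' @export
classify_mito_shape <- function(vertices, image_dim, control = shape_control(),
                                border_tol_px = 1) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stopf("an outline needs at least 3 vertices")
  if (any(vertices[, 1] <= border_tol_px | vertices[, 2] <= border_tol_px |
          vertices[, 1] >= image_dim[1] - border_tol_px + 1 |
          vertices[, 2] >= image_dim[2] - border_tol_px + 1))
    return("partial")
  mom <- polygon_moments(vertices)
  ev <- eigen(mom$cov, symmetric = TRUE, only.values = TRUE)$values
  aspect <- sqrt(max(ev) / max(min(ev), .Machine$double.eps))
  hull <- grDevices::chull(vertices)
  solidity <- mom$area / abs(shoelace(vertices[hull, , drop = FALSE]))
  if (solidity < control$solidity_min) return("polygon")
  if (aspect < control$aspect_min) "round" else "ellipsoidal"
}

## Area, centroid and covariance of a simple polygon (closed-form moments).
polygon_moments <- function(v) {
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  a <- x * y2 - x2 * y
  A <- sum(a) / 2
  cx <- sum((x + x2) * a) / (6 * A)
  cy <- sum((y + y2) * a) / (6 * A)
  Ixx <- sum((x^2 + x * x2 + x2^2) * a) / 12
  Iyy <- sum((y^2 + y * y2 + y2^2) * a) / 12
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * a) / 24
  covm <- matrix(c(Ixx / A - cx^2, Ixy / A - cx * cy,
                   Ixy / A - cx * cy, Iyy / A - cy^2), 2, 2)
  list(area = abs(A), centroid = c(cx, cy), cov = covm)
}

shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}
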