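# 3D morphometrics and the cristae shape taxonomy.

label_map <- c(background = 0L, omm = 1L, ibm = 2L, crista_membrane = 3L,
               matrix = 4L, ims = 5L, cristae_lumen = 6L)

## Hand-built slab component: membranes at z-layers 1:2 and 7:8, lumen 3:6,
## optionally collapsed (membrane-filled) over an x-range across all depths.
ribbon_component <- function(len_x = 30L, dep_y = 60L, closed_x = integer(),
                             vox = 2.2) {
  rows <- list(); lum <- list()
  for (x in seq_len(len_x)) for (zl in 1:8) {
    is_lumen <- zl >= 3 && zl <= 6 && !(x %in% closed_x)
    is_mem <- zl <= 2 || zl >= 7 || (x %in% closed_x)
    if (is_lumen || is_mem) {
      rows[[length(rows) + 1L]] <- cbind(x, seq_len(dep_y), zl)
      lum[[length(lum) + 1L]] <- rep(is_lumen, dep_y)
    }
  }
  list(coords = do.call(rbind, rows), lumen = unlist(lum),
       crista_id = 1L, voxel_size_nm = vox)
}

test_that("compartment volumes recover the closed-form sphere geometry", {
  ph <- cached("volume_phantom", function()
    sphere_phantom(list(crista_spec("globular", 70,
                                    center_nm = phantom_center()))))
  cv <- compartment_volumes(ph$labels)
  tv <- ph$truth$volumes
  expect_true(tv$exact)
  expect_lt(abs(cv$matrix_um3 - tv$matrix_um3) / tv$matrix_um3, 0.02)
  expect_lt(abs(cv$ims_um3 - tv$ims_um3) / tv$ims_um3, 0.02)
  expect_lt(abs(cv$cl_um3 - tv$cl_um3) / tv$cl_um3, 0.02)
  expect_identical(cv$total_um3, cv$matrix_um3 + cv$ims_um3 + cv$cl_um3)
})

test_that("degenerate and malformed label volumes are handled", {
  empty <- structure(list(data = array(0L, rep(10, 3)), voxel_size_nm = 2,
                          map = label_map, crista_id = NULL),
                     class = "label_volume")
  cv <- compartment_volumes(empty)
  expect_equal(cv$total_um3, 0)
  expect_true(is.na(cv$ratios$cl))
  bad <- empty; bad$map <- label_map[c("background", "matrix")]
  expect_error(compartment_volumes(bad), "ims")
})

test_that("polyline lengths are exact, isometry-invariant, and match arcs", {
  expect_equal(crista_length(rbind(c(0, 0, 0), c(100, 0, 0)), 2.2), 220)
  th <- seq(0, pi, length.out = 65)
  r_vox <- 50 / 2.2
  semi <- cbind(r_vox * cos(th), r_vox * sin(th), 0)
  expect_lt(abs(crista_length(semi, 2.2) - pi * 50) / (pi * 50), 0.01)
  R <- cristamorph:::rotation_axis_angle(c(1, 1, 1), 35)
  expect_equal(crista_length(semi %*% t(R), 2.2), crista_length(semi, 2.2))
  expect_error(crista_length(rbind(c(0, 0, 0)), 2.2), "2 points")
})

test_that("the centerline of a straight ribbon matches the planted length", {
  ctr <- phantom_center()
  # narrow slab: its longest geodesic is the planted length (the membrane
  # caps and lattice path add only a few percent)
  cs <- crista_spec("lamellar", 15, 160, 16, ctr, c(1, 0, 0),
                    direction = c(0, 1, 0))
  ph <- sphere_phantom(list(cs))
  comp <- crista_components(ph$labels)[[1]]
  sk <- skeletonize_crista(comp)
  expect_false(sk$is_ring)
  expect_lt(abs(sk$length_nm - 160) / 160, 0.05)
  expect_identical(skeletonize_crista(comp)$polyline, sk$polyline)
})

test_that("ring cristae are detected as closed cycles with a sensible circumference", {
  ex <- exemplar_classifications()
  sk <- skeletonize_crista(ex$ring$comp)
  expect_true(sk$is_ring)
  expect_lt(abs(sk$length_nm - 2 * pi * 40) / (2 * pi * 40), 0.25)
})

test_that("the classifier recovers every planted shape class", {
  ex <- exemplar_classifications()
  got_class <- vapply(ex, function(e) e$cl$shape_class, character(1))
  got_sub <- vapply(ex, function(e) e$cl$unusual_subclass, character(1))
  expect_equal(unname(got_class[c("lamellar", "tubular", "globular")]),
               c("lamellar", "tubular", "globular"))
  expect_equal(unname(got_sub[c("lamellar", "tubular", "globular")]),
               rep("none", 3))
  expect_equal(unname(got_class[c("ring", "loop", "straight_across", "split")]),
               rep("unusual", 4))
  expect_equal(unname(got_sub[c("ring", "loop", "straight_across", "split")]),
               c("ring", "loop", "straight_across", "split"))
})

test_that("classification is invariant to rigid motion of the label volume", {
  ctr <- phantom_center()
  cs1 <- crista_spec("lamellar", 15, 100, 100, ctr, c(1, 0, 0))
  cs2 <- crista_spec("lamellar", 15, 100, 100, ctr + c(6, -4, 9),
                     orientation = cristamorph:::unit(c(1, 1, 0.3)))
  for (cs in list(cs1, cs2)) {
    ph <- sphere_phantom(list(cs))
    comp <- crista_components(ph$labels)[[1]]
    expect_equal(classify_shape(comp)$shape_class, "lamellar")
  }
})

test_that("zipped and pinched cristae are separated by collapse length", {
  # 14 collapsed voxels = 30.8 nm >= 20 nm -> zipped
  zipped <- ribbon_component(closed_x = 9:22)
  clz <- classify_shape(zipped)
  expect_equal(clz$unusual_subclass, "zipped")
  # 4 collapsed voxels = 8.8 nm < 20 nm -> pinched
  pinched <- ribbon_component(closed_x = 14:17)
  clp <- classify_shape(pinched)
  expect_equal(clp$unusual_subclass, "pinched")
  # open ribbon classifies by canonical geometry (lamellar), not collapse
  open_r <- ribbon_component()
  expect_equal(classify_shape(open_r)$shape_class, "lamellar")
  expect_equal(classify_shape(open_r)$unusual_subclass, "none")
})

test_that("vesicular cristae are flagged by lumen density contrast", {
  # spherical crista: membrane shell radius 8-10, lumen inside
  g <- expand.grid(x = 1:40, y = 1:40, z = 1:40)
  r <- sqrt((g$x - 20)^2 + (g$y - 20)^2 + (g$z - 20)^2)
  mem <- r >= 8 & r <= 10
  lum <- r < 8
  lab <- array(label_map[["matrix"]], rep(40, 3))
  lab[mem] <- label_map[["crista_membrane"]]
  lab[lum] <- label_map[["cristae_lumen"]]
  cid <- array(0L, rep(40, 3)); cid[mem | lum] <- 1L
  labels <- structure(list(data = lab, voxel_size_nm = 2.2, map = label_map,
                           crista_id = cid), class = "label_volume")
  dens_filled <- array(0, rep(40, 3)); dens_filled[mem] <- -1; dens_filled[lum] <- -0.8
  dens_empty <- array(0, rep(40, 3)); dens_empty[mem] <- -1
  comp <- crista_components(labels)[[1]]
  c_filled <- crista_lumen_contrast(comp, tomogram(dens_filled, 2.2), labels)
  c_empty <- crista_lumen_contrast(comp, tomogram(dens_empty, 2.2), labels)
  expect_lt(c_filled, 0.6)
  expect_gt(c_empty, 0.9)
  expect_equal(classify_shape(comp, lumen_contrast = c_filled)$unusual_subclass,
               "vesicular")
  expect_equal(classify_shape(comp, lumen_contrast = c_empty)$shape_class,
               "globular")
})

test_that("irregular blobs fall through to amorphous", {
  g <- expand.grid(x = 1:40, y = 1:24, z = 1:16)
  keep <- ((g$x - 20)^2 / 20^2 + (g$y - 12)^2 / 12^2 + (g$z - 8)^2 / 8^2) <= 1
  comp <- list(coords = as.matrix(g[keep, ]), lumen = rep(FALSE, sum(keep)),
               crista_id = 1L, voxel_size_nm = 2.2)
  cl <- classify_shape(comp)
  expect_equal(cl$shape_class, "unusual")
  expect_equal(cl$unusual_subclass, "amorphous")
})

test_that("directionality follows the junction-angle rule", {
  expect_equal(classify_directionality(0), "NAO")
  expect_equal(classify_directionality(1, 90), "straight")
  expect_equal(classify_directionality(1, 45), "tilted")
  expect_equal(classify_directionality(2, c(85, 100)), "straight")
  # widening the tolerance can only move cristae from tilted to straight
  angs <- c(60, 75, 88)
  lab10 <- classify_directionality(3, angs, tilt_tolerance_deg = 10)
  lab35 <- classify_directionality(3, angs, tilt_tolerance_deg = 35)
  expect_equal(lab10, "tilted")
  expect_equal(lab35, "straight")
})

test_that("multijunction cristae split into straight and loop by straightness", {
  expect_equal(classify_multijunction(1, 0.99), "none")
  expect_equal(classify_multijunction(2, 0.99), "straight")
  expect_equal(classify_multijunction(2, 0.6), "loop")
  ex <- exemplar_classifications()
  expect_equal(classify_multijunction(2, ex$straight_across$cl$descriptors$straightness),
               "straight")
  expect_equal(classify_multijunction(2, ex$loop$cl$descriptors$straightness),
               "loop")
})

test_that("stacking requires three near-parallel overlapping lamellar cristae", {
  ctr <- phantom_center()
  mk_stack <- function(middle_normal) {
    specs <- list(
      crista_spec("lamellar", 15, 80, 80, ctr - c(25, 0, 0), c(1, 0, 0)),
      crista_spec("lamellar", 15, 80, 80, ctr, middle_normal),
      crista_spec("lamellar", 15, 80, 80, ctr + c(25, 0, 0), c(1, 0, 0)))
    ph <- sphere_phantom(specs)
    lapply(crista_components(ph$labels), function(comp) {
      cl <- classify_shape(comp)
      list(shape_class = cl$shape_class, normal = cl$descriptors$normal,
           coords = comp$coords)
    })
  }
  parallel3 <- cached("stack_parallel", function() mk_stack(c(1, 0, 0)))
  expect_true(detect_stacking(parallel3))
  expect_false(detect_stacking(parallel3[1:2]))          # only two cristae
  rotated <- cached("stack_rotated", function()
    mk_stack(cristamorph:::unit(c(1, 0, 1))))            # middle sheet at 45 deg
  expect_false(detect_stacking(rotated))
})

test_that("mitochondrion outlines classify into the four 2D shape classes", {
  circle <- ellipse_outline(c(300, 300), c(600, 600), 10)
  expect_equal(classify_mito_shape(circle, c(120, 120)), "round")
  ell <- ellipse_outline(c(400, 200), c(600, 600), 10)
  expect_equal(classify_mito_shape(ell, c(120, 120)), "ellipsoidal")
  clipped <- ellipse_outline(c(300, 300), c(80, 600), 10)
  expect_equal(classify_mito_shape(clipped, c(120, 120)), "partial")
  # deeply concave outline: low solidity
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  r <- 40 * (1 + 0.45 * cos(4 * th))
  star <- cbind(60 + r * cos(th), 60 + r * sin(th))
  expect_equal(classify_mito_shape(star, c(120, 120)), "polygon")
  expect_error(classify_mito_shape(circle[1:2, ], c(120, 120)), "3 vertices")
})
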