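# Phantom generator: geometry, rendering levels, ground truth, wedge, sampling.

test_that("a crista-free phantom has no crista labels and clean volumes", {
  ph <- sphere_phantom(box = 80L, radius_nm = 75)
  lab <- ph$labels
  expect_equal(sum(lab$data == lab$map[["crista_membrane"]]), 0)
  expect_equal(sum(lab$data == lab$map[["cristae_lumen"]]), 0)
  # voxel-count compartments vs closed-form truth (sphere: exact offsets)
  cv <- compartment_volumes(lab)
  tv <- ph$truth$volumes
  expect_lt(abs(cv$matrix_um3 - tv$matrix_um3) / tv$matrix_um3, 0.02)
  expect_lt(abs(cv$ims_um3 - tv$ims_um3) / tv$ims_um3, 0.02)
  expect_identical(cv$total_um3, cv$matrix_um3 + cv$ims_um3 + cv$cl_um3)
})

test_that("a planted lamellar crista reproduces its width in the density profile", {
  ctr <- phantom_center()
  cs <- crista_spec("lamellar", 15, 120, 120, ctr, c(1, 0, 0))
  ph <- sphere_phantom(list(cs))
  vox <- ph$tomogram$voxel_size_nm
  prof <- ph$tomogram$data[, 60, 60]
  x_nm <- (seq_along(prof) - 0.5) * vox
  sel <- abs(x_nm - ctr[1]) < 25
  troughs <- profile_trough_positions(prof[sel]) + which(sel)[1] - 1
  expect_length(troughs, 2)
  gap_nm <- diff(troughs) * vox
  expect_lt(abs(gap_nm - 15), vox)  # trough-to-trough = planted width +/- 1 voxel
})

test_that("the noiseless render is two-valued up to anti-aliased boundaries", {
  ctr <- phantom_center()
  cs <- crista_spec("lamellar", 15, 60, 60, ctr, c(1, 0, 0))
  ph <- generate_phantom(phantom_spec(
    box_shape = c(120, 120, 120), voxel_size_nm = 2.2,
    omm_semi_axes_nm = c(70, 70, 70), center_nm = ctr, cristae = list(cs),
    noise_sigma = 0, wedge_half_angle_deg = 0))
  v <- ph$tomogram$data
  at_levels <- mean(abs(v - 0) < 1e-9 | abs(v - (-1)) < 1e-9)
  expect_gt(at_levels, 0.95)
  expect_true(all(v >= -1 - 1e-9 & v <= 1e-9))
})

test_that("membrane label voxels are dark and interior ones sit at the membrane level", {
  ctr <- phantom_center()
  cs <- crista_spec("lamellar", 15, 100, 100, ctr, c(1, 0, 0))
  ph <- sphere_phantom(list(cs))
  lab <- ph$labels
  mem <- lab$data == lab$map[["crista_membrane"]]
  expect_true(all(ph$tomogram$data[mem] < -0.4))
  # voxels in the membrane mid-plane render exactly at membrane_density
  expect_true(any(abs(ph$tomogram$data[mem] - (-1)) < 1e-9))
})

test_that("phantoms are bit-identical under the same spec and seed", {
  mk <- function() sphere_phantom(box = 60L, radius_nm = 55,
                                  noise_sigma = 0.7, wedge = 20, seed = 42L)
  expect_identical(mk()$tomogram$data, mk()$tomogram$data)
})

test_that("invalid geometry is rejected with informative errors", {
  ctr <- phantom_center(60L)
  too_big <- crista_spec("lamellar", 15, 200, 200, ctr, c(1, 0, 0))
  expect_error(
    generate_phantom(phantom_spec(rep(60L, 3), 2.2, rep(55, 3), center_nm = ctr,
                                  cristae = list(too_big))),
    "exceeds the IBM")
  expect_error(phantom_spec(rep(60L, 3), voxel_size_nm = 0, rep(55, 3)),
               "voxel_size_nm")
  expect_error(phantom_spec(rep(60L, 3), 2.2, rep(55, 3), membrane_density = 1,
                            solvent_density = 0),
               "darker")
  expect_error(crista_spec("loop", 15, 100,
                           junctions = list(list(angle_deg = 90, width_nm = 10))),
               "exactly 2 junctions")
  expect_error(crista_spec("lamellar", 15, 100,
                           junctions = list(list(angle_deg = 190, width_nm = 10))),
               "angle")
})

test_that("the missing wedge is an idempotent projection with the right power loss", {
  set.seed(9)
  v <- tomogram(array(rnorm(40^3), rep(40, 3)), 2.2)
  expect_equal(apply_missing_wedge(v, 0)$data, v$data)
  w <- apply_missing_wedge(v, 20)
  ww <- apply_missing_wedge(w, 20)
  expect_equal(ww$data, w$data, tolerance = 1e-10)
  # white noise: fraction of power removed matches the masked-voxel fraction
  removed <- 1 - sum(Mod(fft(w$data))^2) / sum(Mod(fft(v$data))^2)
  mask_frac <- mean(missing_wedge_mask(rep(40, 3), 20))
  expect_lt(abs(removed - mask_frac), 0.02)
  expect_true(is.numeric(w$data) && !is.complex(w$data))
  expect_error(apply_missing_wedge(v, 95), "0, 90")
})

test_that("particle sampling is seeded, on-membrane, and bounded by site count", {
  ctr <- phantom_center()
  cs <- crista_spec("lamellar", 15, 100, 100, ctr, c(1, 0, 0))
  ph <- cached("sampling_phantom", function() sphere_phantom(list(cs)))
  expect_equal(nrow(sample_particles(ph$labels, ph$truth, 0)), 0)
  p1 <- sample_particles(ph$labels, ph$truth, 25, seed = 5)
  p2 <- sample_particles(ph$labels, ph$truth, 25, seed = 5)
  expect_identical(p1, p2)
  # every sampled position lies within one voxel of a lumen/membrane voxel
  lab <- ph$labels
  ok <- vapply(seq_len(nrow(p1)), function(i) {
    ix <- round(c(p1$x[i], p1$y[i], p1$z[i]))
    box <- lab$data[max(1, ix[1] - 1):(ix[1] + 1),
                    max(1, ix[2] - 1):(ix[2] + 1),
                    max(1, ix[3] - 1):(ix[3] + 1)]
    any(box %in% c(lab$map[["cristae_lumen"]], lab$map[["crista_membrane"]]))
  }, logical(1))
  expect_true(all(ok))
  expect_error(sample_particles(ph$labels, ph$truth, 1e6), "available")
})

test_that("ground-truth junction records echo the planted junction geometry", {
  ctr <- phantom_center()
  cs <- crista_spec("straight_across", 15, 180, 80, ctr, c(1, 0, 0),
                    junctions = list(list(angle_deg = 70, width_nm = 18),
                                     list(angle_deg = 90, width_nm = 22)))
  ph <- sphere_phantom(list(cs))
  j <- ph$truth$junctions
  expect_equal(nrow(j), 2)
  expect_equal(j$angle_deg, c(70, 90))
  expect_equal(j$width_nm, c(18, 22))
  expect_equal(ph$truth$cristae$n_junctions, 2)
})
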