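# Template bank, width estimation, extraction, alignment and averaging.

test_that("the default bank spans 2.2-88 nm with zero-mean templates", {
  bank <- template_bank()
  expect_equal(bank$n_templates, 40L)
  expect_equal(bank$separations_nm[1], 2.2)
  expect_equal(bank$separations_nm[40], 88)
  expect_equal(diff(bank$separations_nm), rep(2.2, 39))
  expect_true(all(abs(colMeans(bank$profiles)) < 1e-12))
  expect_error(template_bank(n_templates = 50, box = 48), "fit")
})

test_that("template axial profiles have troughs separated by exactly k pixels", {
  bank <- template_bank()
  # membranes are resolved once the separation exceeds the membrane thickness
  for (k in c(3, 7, 16, 33, 40)) {
    troughs <- profile_trough_positions(bank$profiles[, k])
    expect_length(troughs, 2)
    expect_equal(diff(troughs), k, tolerance = 1e-9)
  }
})

test_that("self-match identity: every template recovers its own separation with cc 1", {
  bank <- template_bank()
  for (k in seq_len(bank$n_templates)) {
    r <- estimate_width(template_volume(bank, k), bank)
    expect_equal(r$template_index, k)
    expect_equal(r$width_nm, k * 2.2)
    expect_equal(r$cc_peak, 1, tolerance = 1e-6)
  }
})

test_that("the 1D profile reduction equals brute-force 3D masked NCC", {
  bank <- template_bank(n_templates = 12, box = 24)
  particle <- template_volume(bank, 5)
  r <- estimate_width(particle, bank, shift_bound_px = 0)
  brute <- vapply(seq_len(bank$n_templates), function(k)
    cristamorph:::masked_ncc(particle, template_volume(bank, k), bank$mask),
    numeric(1))
  expect_equal(r$cc_by_template, brute, tolerance = 1e-12)
})

test_that("cc scores always lie in [-1, 1]", {
  bank <- template_bank(n_templates = 12, box = 24)
  set.seed(4)
  for (i in 1:5) {
    particle <- array(rnorm(24^3), rep(24, 3))
    r <- estimate_width(particle, bank)
    expect_true(all(r$cc_by_template >= -1 - 1e-9 & r$cc_by_template <= 1 + 1e-9))
  }
})

test_that("extraction copies subvolumes, recenters deltas, and drops boundary picks", {
  const <- tomogram(array(7, c(40, 40, 40)), 2.2)
  pos <- data.frame(x = 20, y = 20, z = 20)
  ps <- extract_subtomograms(const, pos, box = 16)
  expect_equal(ps$subvolumes[[1]], array(7, rep(16, 3)))
  # delta voxel appears at the subvolume centre
  d <- array(0, c(40, 40, 40)); d[23, 18, 21] <- 1
  ps2 <- extract_subtomograms(tomogram(d, 2.2),
                              data.frame(x = 23, y = 18, z = 21), box = 16)
  ctr <- 16L %/% 2L
  expect_equal(which(ps2$subvolumes[[1]] == 1, arr.ind = TRUE)[1, ],
               c(dim1 = ctr, dim2 = ctr, dim3 = ctr))
  # boundary-crossing positions are dropped and counted
  pos3 <- data.frame(x = c(20, 2, 39), y = c(20, 20, 20), z = c(20, 20, 20))
  expect_warning(ps3 <- extract_subtomograms(const, pos3, box = 16), "dropped")
  expect_equal(length(ps3$subvolumes), 1)
  expect_equal(ps3$dropped, 2L)
})

test_that("axis-aligned normals are brought to the template frame exactly", {
  bank <- template_bank(n_templates = 12, box = 24)
  tpl <- template_volume(bank, 6)
  vol <- aperm(tpl, c(3, 2, 1))   # membranes now stacked along x
  big <- array(0, c(60, 60, 60))
  big[19:42, 19:42, 19:42] <- vol
  pos <- data.frame(x = 30, y = 30, z = 30, nx = 1, ny = 0, nz = 0)
  ps <- extract_subtomograms(tomogram(big, 2.2), pos, box = 24)
  r <- estimate_width(ps$subvolumes[[1]], bank)
  expect_equal(r$template_index, 6)
})

test_that("identical particles are a fixed point of alignment", {
  bank <- template_bank(n_templates = 12, box = 24)
  tpl <- template_volume(bank, 6)
  ps <- structure(list(subvolumes = lapply(1:4, function(i) tpl),
                       positions = data.frame(id = 1:4), box = 24L,
                       pixel_size_nm = 2.2, dropped = 0L),
                  class = "particle_set")
  res <- align_and_average(ps, seed = 1)
  expect_length(res$average$cc_trace, 1)     # converges immediately
  expect_true(res$average$converged)
  expect_equal(res$average$density, tpl)
  expect_true(all(res$particles$positions[, c("shift_x", "shift_y", "shift_z")] == 0))
})

test_that("planted integer shifts are recovered exactly on noiseless copies", {
  box <- 24L
  ref <- structured_volume(box, seed = 77)
  base <- matrix(c(3, -2, 4, 1, 0, -3, -4, 2, 1, 2, -1, 0, 0, 4, -2), 5, 3)
  planted <- rbind(base, -base)               # zero net drift by construction
  subs <- lapply(seq_len(nrow(planted)), function(i)
    cristamorph:::shift_volume(ref, planted[i, ]))
  ps <- structure(list(subvolumes = subs,
                       positions = data.frame(id = seq_len(nrow(planted))),
                       box = box, pixel_size_nm = 2.2, dropped = 0L),
                  class = "particle_set")
  res <- align_and_average(ps, n_iter = 12, shift_bound_px = 8, seed = 5)
  rec <- as.matrix(res$particles$positions[, c("shift_x", "shift_y", "shift_z")])
  dimnames(rec) <- NULL
  expect_equal(rec, -planted)
  expect_true(all(diff(res$average$cc_trace) >= -1e-6))
  expect_lte(length(res$average$cc_trace), 12)
  mask <- cristamorph:::soft_spherical_mask(box)
  expect_gt(cristamorph:::masked_ncc(res$average$density, ref, mask), 0.99)
})

test_that("alignment is deterministic under a fixed seed", {
  box <- 24L
  ref <- structured_volume(box, seed = 13)
  set.seed(31)
  subs <- lapply(1:6, function(i)
    cristamorph:::shift_volume(ref, sample(-3:3, 3, replace = TRUE)) +
      array(rnorm(box^3, sd = 0.1), rep(box, 3)))
  mkps <- function() structure(list(subvolumes = subs,
                                    positions = data.frame(id = 1:6), box = box,
                                    pixel_size_nm = 2.2, dropped = 0L),
                               class = "particle_set")
  r1 <- align_and_average(mkps(), seed = 8)
  r2 <- align_and_average(mkps(), seed = 8)
  expect_identical(r1$average$density, r2$average$density)
  expect_identical(r1$particles$positions, r2$particles$positions)
  expect_error(align_and_average(structure(list(
    subvolumes = subs[1], positions = data.frame(id = 1), box = box,
    pixel_size_nm = 2.2, dropped = 0L), class = "particle_set")), "at least 2")
})

test_that("orientation refinement recovers a tilted membrane stack", {
  bank <- template_bank(n_templates = 10, box = 24)
  tpl <- template_volume(bank, 6)
  R <- cristamorph:::rotation_axis_angle(c(0, 1, 0), 30)
  tilted <- cristamorph:::rotate_volume(tpl, R)
  r_plain <- estimate_width(tilted, bank)
  r_ref <- estimate_width(tilted, bank, refine_orientation = TRUE)
  expect_gt(r_ref$cc_peak, r_plain$cc_peak)
  expect_equal(r_ref$template_index, 6)
})

test_that("width estimates are strictly monotone in planted separation", {
  bank <- template_bank()
  got <- vapply(c(3, 6, 9), function(k)
    estimate_width(template_volume(bank, k), bank)$width_nm, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_equal(got, c(3, 6, 9) * 2.2)
})

test_that("the average map width agrees with the per-particle mode on noiseless sets", {
  bank <- template_bank(n_templates = 12, box = 24)
  tpl <- template_volume(bank, 7)
  subs <- lapply(1:5, function(i) tpl)
  ps <- structure(list(subvolumes = subs, positions = data.frame(id = 1:5),
                       box = 24L, pixel_size_nm = 2.2, dropped = 0L),
                  class = "particle_set")
  res <- align_and_average(ps, seed = 2)
  avg_w <- measure_average_width(res$average, bank)
  ps <- estimate_widths(ps, bank)
  mode_w <- as.numeric(names(which.max(table(ps$positions$width_nm))))
  expect_equal(avg_w$width_nm, mode_w)
  expect_equal(avg_w$width_nm, 7 * 2.2)
})

test_that("width tables and histograms conserve observations", {
  expect_error(width_histogram(numeric()), "nonempty")
  h1 <- width_histogram(22, bin_nm = 2.2)
  expect_equal(sum(h1$count), 1)
  expect_equal(h1$count[h1$bin_lo <= 22 & h1$bin_hi > 22], 1)
  set.seed(6)
  w <- runif(137, 0, 50)
  for (b in c(1, 2.2, 5)) expect_equal(sum(width_histogram(w, b)$count), 137)
  # bimodal planted mixture (bin-centred modes at 5.5 and 12.5 steps)
  wm <- c(rep(12.1, 30), rep(27.5, 45)) + rnorm(75, sd = 0.2)
  h <- width_histogram(wm, 2.2)
  top2 <- h[order(-h$count)[1:2], "bin_lo"]
  expect_equal(sort(top2), c(11, 26.4))
})

test_that("pixel-size and box mismatches are rejected", {
  bank <- template_bank(n_templates = 10, box = 24)
  expect_error(estimate_width(array(0, rep(20, 3)), bank), "box")
  ps <- structure(list(subvolumes = list(array(0, rep(24, 3))),
                       positions = data.frame(id = 1), box = 24L,
                       pixel_size_nm = 1.1, dropped = 0L),
                  class = "particle_set")
  expect_error(estimate_widths(ps, bank), "pixel size")
})
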