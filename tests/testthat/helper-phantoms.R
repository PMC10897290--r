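# Shared fixture builders and independent oracles.  Everything is generated
# in code; a session-level cache avoids re-rendering the exemplar phantoms
# across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## A spherical phantom (exact closed-form compartment geometry) with optional
## cristae, noiseless and wedge-free unless stated.
sphere_phantom <- function(cristae = list(), box = 120L, radius_nm = 110,
                           noise_sigma = 0, wedge = 0, seed = 1L,
                           voxel_size_nm = 2.2) {
  ctr <- rep(box * voxel_size_nm / 2, 3)
  generate_phantom(phantom_spec(
    box_shape = rep(box, 3), voxel_size_nm = voxel_size_nm,
    omm_semi_axes_nm = rep(radius_nm, 3), center_nm = ctr,
    cristae = cristae, noise_sigma = noise_sigma,
    wedge_half_angle_deg = wedge, seed = seed))
}

phantom_center <- function(box = 120L, voxel_size_nm = 2.2)
  rep(box * voxel_size_nm / 2, 3)

two_junctions <- function() list(list(angle_deg = 90, width_nm = 20),
                                 list(angle_deg = 90, width_nm = 20))

## One exemplar crista spec per planted shape class, sized to fit the default
## 110 nm sphere.
exemplar_specs <- function() {
  ctr <- phantom_center()
  list(
    lamellar = crista_spec("lamellar", 15, 120, 120, ctr, c(1, 0, 0)),
    tubular = crista_spec("tubular", 25, 150, center_nm = ctr,
                          orientation = c(1, 0, 0)),
    globular = crista_spec("globular", 60, center_nm = ctr),
    ring = crista_spec("ring", 15, 2 * pi * 40, center_nm = ctr,
                       orientation = c(0, 1, 0)),
    loop = crista_spec("loop", 15, pi * 50, depth_nm = 100,
                       center_nm = ctr - c(0, 0, 32),
                       orientation = c(0, 1, 0), junctions = two_junctions()),
    straight_across = crista_spec("straight_across", 15, 180, 80, ctr,
                                  c(1, 0, 0), junctions = two_junctions()),
    split = crista_spec("split", 15, 120, 80, ctr, c(1, 0, 0),
                        branch_length_nm = 60)
  )
}

## Classify every exemplar (cached: rendering seven phantoms is the slow part).
exemplar_classifications <- function() {
  cached("exemplar_classifications", function() {
    lapply(exemplar_specs(), function(cs) {
      ph <- sphere_phantom(list(cs))
      comp <- crista_components(ph$labels)[[1]]
      cl <- classify_shape(comp, n_junctions = ph$truth$cristae$n_junctions[1])
      list(cl = cl, comp = comp, truth = ph$truth)
    })
  })
}

## Independent Mann-Whitney oracle: two-sided p by full enumeration over all
## C(n_a + n_b, n_a) labelings of the pooled sample (tie-free data).
enum_mann_whitney_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  stat <- function(idx) sum(rk[idx]) - na * (na + 1) / 2
  u_obs <- stat(seq_len(na))
  mid <- na * length(b) / 2
  labelings <- utils::combn(length(pooled), na)
  us <- apply(labelings, 2, stat)
  mean(abs(us - mid) >= abs(u_obs - mid))
}

## Point-in-polygon rasterization count at half-pixel resolution (even-odd
## rule); oracle for the shoelace area.
rasterized_polygon_area <- function(vertices, pixel_size_nm, step = 0.5) {
  xr <- range(vertices[, 1]); yr <- range(vertices[, 2])
  xs <- seq(xr[1] - 1, xr[2] + 1, by = step)
  ys <- seq(yr[1] - 1, yr[2] + 1, by = step)
  g <- expand.grid(x = xs, y = ys)
  n <- nrow(vertices)
  inside <- rep(FALSE, nrow(g))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    cross <- ((yi > g$y) != (yj > g$y)) &
      (g$x < (xj - xi) * (g$y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  sum(inside) * step^2 * pixel_size_nm^2 * 1e-6
}

## Trough positions of a 1D profile: midpoint of each flat minimum run.
profile_trough_positions <- function(p) {
  lo <- which(p < min(p) + 1e-9)
  splits <- split(lo, cumsum(c(1, diff(lo) > 1)))
  unname(vapply(splits, function(ix) mean(ix), numeric(1)))
}

## Band-limited random volume: a 3D-structured particle for planted-transform
## alignment tests (laterally constant templates cannot pin x/y shifts).
structured_volume <- function(box, seed, sigma = 2) {
  set.seed(seed)
  v <- array(stats::rnorm(box^3), rep(box, 3))
  cristamorph:::gaussian_smooth3(v, sigma)
}
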