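# Projection-plane morphometrics: mitochondrial area and coverage, cristae
# density, matrix gray density, junction width and angle.  These mirror the
# manual FIJI measurements made on summed projection images; the localization
# of what to measure (outlines, probe lines, junction endpoints) is input, not
# auto-detected.

#' Polygon area in square micrometres
#'
#' Shoelace area of an outline drawn in pixel coordinates, scaled by the pixel
#' size; orientation-independent.
#'
#' @param vertices n x 2 matrix of ordered outline vertices (pixels).
#' @param pixel_size_nm pixel edge (nm).
#' @return area in um^2.
#' @export
polygon_area <- function(vertices, pixel_size_nm) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stopf("a polygon needs at least 3 vertices")
  if (pixel_size_nm <= 0) stopf("`pixel_size_nm` must be > 0")
  if (polygon_self_intersects(vertices)) stopf("polygon is self-intersecting")
  a2 <- abs(shoelace(vertices))
  if (a2 < .Machine$double.eps) stopf("vertices are collinear")
  a2 * pixel_size_nm^2 * 1e-6   # nm^2 -> um^2
}

## O(n^2) proper-crossing test between non-adjacent edges.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip adjacent (wrap) edge
    if (!length(js)) next
    p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
    q1x <- seg[js, 1]; q1y <- seg[js, 2]; q2x <- seg[js, 3]; q2y <- seg[js, 4]
    d1 <- cross2(p1[1], p1[2], p2[1], p2[2], q1x, q1y)
    d2 <- cross2(p1[1], p1[2], p2[1], p2[2], q2x, q2y)
    d3 <- cross2(q1x, q1y, q2x, q2y, p1[1], p1[2])
    d4 <- cross2(q1x, q1y, q2x, q2y, p2[1], p2[2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Mitochondrial coverage of the imaged field
#'
#' @param area_um2 mitochondrial area (um^2).
#' @param image the [image2d()] the outline was drawn on.
#' @return the dimensionless fraction of the field covered.
#' @export
mito_coverage <- function(area_um2, image) {
  stopifnot(inherits(image, "image2d"))
  field <- prod(dim(image$data)) * image$pixel_size_nm^2 * 1e-6
  if (field <= 0) stopf("image has zero area")
  if (area_um2 > field + 1e-12)
    stopf("mitochondrial area (%.4g um^2) exceeds the field (%.4g um^2)",
          area_um2, field)
  area_um2 / field
}

#' Cristae density
#'
#' Number of cristae normalized by mitochondrial area.
#'
#' @param n_cristae crista count (>= 0).
#' @param area_um2 mitochondrial area (um^2, > 0).
#' @return cristae per um^2.
#' @export
cristae_density <- function(n_cristae, area_um2) {
  if (area_um2 <= 0) stopf("`area_um2` must be > 0")
  if (n_cristae < 0) stopf("`n_cristae` must be >= 0")
  n_cristae / area_um2
}

#' Matrix gray density from three probe lines
#'
#' Means the gray values along exactly three line probes drawn in the matrix
#' region of a contrast-normalized projection image (bilinear interpolation at
#' steps of at most half a pixel), then means the three per-line values.
#'
#' @param image a contrast-normalized [image2d()] (see [normalize_contrast()]).
#' @param probes list of exactly 3 segments, each `list(p1 =, p2 =)` in pixel
#'   coordinates.
#' @return the mean gray value (one number per mitochondrial matrix).
#' @export
matrix_density <- function(image, probes) {
  stopifnot(inherits(image, "image2d"))
  if (length(probes) != 3L) stopf("exactly 3 probe lines are required, got %d",
                                  length(probes))
  vals <- vapply(probes, function(pr) {
    line_mean(image$data, pr$p1, pr$p2)
  }, numeric(1))
  mean(vals)
}

## Mean of bilinear samples along a segment at <= 0.5 px spacing.
line_mean <- function(img, p1, p2) {
  d <- dim(img)
  if (any(c(p1, p2) < 1) || p1[1] > d[1] || p2[1] > d[1] ||
      p1[2] > d[2] || p2[2] > d[2])
    stopf("probe line outside the image")
  len <- sqrt(sum((p2 - p1)^2))
  nstep <- max(1L, ceiling(len / 0.5))
  t_ <- seq(0, 1, length.out = nstep + 1)
  xs <- p1[1] + t_ * (p2[1] - p1[1])
  ys <- p1[2] + t_ * (p2[2] - p1[2])
  mean(bilinear(img, xs, ys))
}

bilinear <- function(img, x, y) {
  d <- dim(img)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' Cristae junction width
#'
#' Euclidean distance between the two membrane points delimiting a junction,
#' in nm.
#'
#' @param p1,p2 junction endpoints (pixel coordinates), distinct.
#' @param pixel_size_nm pixel edge (nm).
#' @return width in nm.
#' @export
junction_width <- function(p1, p2, pixel_size_nm) {
  if (pixel_size_nm <= 0) stopf("`pixel_size_nm` must be > 0")
  d <- sqrt(sum((p2 - p1)^2))
  if (d < .Machine$double.eps) stopf("junction endpoints coincide")
  d * pixel_size_nm
}

#' Cristae junction angle
#'
#' Interior angle at `vertex` between the ray toward `ray_a` (along the local
#' inner boundary membrane) and the ray toward `ray_b` (along the crista
#' axis); a crista perpendicular to the IBM scores 90 degrees.
#'
#' @param vertex angle vertex (pixel coordinates).
#' @param ray_a,ray_b points defining the two rays from the vertex.
#' @return angle in degrees, in (0, 180].
#' @export
junction_angle <- function(vertex, ray_a, ray_b) {
  a <- ray_a - vertex
  b <- ray_b - vertex
  if (sqrt(sum(a^2)) < .Machine$double.eps || sqrt(sum(b^2)) < .Machine$double.eps)
    stopf("zero-length ray")
  angle_between(c(a, 0), c(b, 0))
}

#' Create a junction record
#'
#' A junction visible in multiple non-overlapping sections of a tomogram
#' carries one width and one angle measurement per section; the record's
#' summary values are the means.
#'
#' @param junction_id,crista_id identifiers.
#' @param width_measurements_nm numeric vector of width measurements (nm).
#' @param angle_measurements_deg numeric vector of angle measurements (deg).
#' @return an object of class `junction_record`.
#' @export
junction_record <- function(junction_id, crista_id, width_measurements_nm,
                            angle_measurements_deg) {
  structure(list(junction_id = junction_id, crista_id = crista_id,
                 width_measurements_nm = width_measurements_nm,
                 angle_measurements_deg = angle_measurements_deg,
                 width_nm = NA_real_, angle_deg = NA_real_),
            class = "junction_record")
}

#' Aggregate repeated junction measurements
#'
#' Sets the record's `width_nm` and `angle_deg` to the arithmetic means of the
#' per-section measurement lists, representing the junction's overall 3D
#' shape.
#'
#' @param record a [junction_record()] with at least one width and one angle
#'   measurement.
#' @return the record with summary fields filled.
#' @export
aggregate_junction <- function(record) {
  stopifnot(inherits(record, "junction_record"))
  if (length(record$width_measurements_nm) == 0L ||
      length(record$angle_measurements_deg) == 0L)
    stopf("junction record has empty measurement lists")
  record$width_nm <- mean(record$width_measurements_nm)
  record$angle_deg <- mean(record$angle_measurements_deg)
  record
}

#' Elliptical outline polygon
#'
#' Convenience for building a mitochondrion outline from phantom geometry:
#' vertices of an axis-aligned ellipse in pixel coordinates.
#'
#' @param semi_axes_nm ellipse semi-axes (2 values, nm).
#' @param center_nm ellipse centre (2 values, nm).
#' @param pixel_size_nm pixel edge (nm).
#' @param n number of vertices (default 72).
#' @return an n x 2 matrix of vertices.
#' @export
ellipse_outline <- function(semi_axes_nm, center_nm, pixel_size_nm, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = (center_nm[1] + semi_axes_nm[1] * cos(th)) / pixel_size_nm + 0.5,
        y = (center_nm[2] + semi_axes_nm[2] * sin(th)) / pixel_size_nm + 0.5)
}
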