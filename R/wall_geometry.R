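#' Anatomical orientation of an axial slice
#'
#' In the supine axial convention the image -y axis points to the
#' patient's anterior and the image -x axis to the patient's right.
#' Non-standard slice orientations can supply their own unit axes.
#'
#' @param anterior,right length-2 unit vectors (image mm coordinates).
#' @return orientation object used by [quadrant_of()] and [seed_points()].
#' @export
slice_orientation <- function(anterior = c(0, -1), right = c(-1, 0)) {
  a <- anterior / sqrt(sum(anterior^2))
  r <- right / sqrt(sum(right^2))
  if (abs(sum(a * r)) > 1e-8)
    abort("anterior and right axes must be orthogonal", "parameter_error")
  structure(list(anterior = a, right = r), class = "slice_orientation")
}

#' Circumferential angle about a centre, measured from the anterior axis
#'
#' Returns the angle theta in \[0, 2*pi) with theta = 0 on the anterior
#' (A) axis, increasing towards the right (R) axis, the fixed angular
#' convention used for stretch profiles.
#'
#' @param points n x 2 matrix of (x, y) mm.
#' @param center length-2 centre (mm).
#' @param orientation a [slice_orientation()].
#' @return numeric vector of angles (radians in \[0, 2*pi)).
#' @export
quadrant_angle <- function(points, center,
                           orientation = slice_orientation()) {
  p <- matrix(as.numeric(t(t(as.matrix(points)) - center)), ncol = 2)
  atan2(p %*% orientation$right, p %*% orientation$anterior)[, 1] %% (2 * pi)
}

#' Quadrant label of circumferential positions
#'
#' Divides the circumference into four 90-degree sectors centred on the
#' anatomical axes: anterior (A), right (R), posterior (P), left (L).
#' Sector boundaries lie on the 45-degree diagonals; a point exactly on a
#' boundary is assigned to the next sector in the direction of
#' increasing angle (so the A/R diagonal belongs to R).
#'
#' @inheritParams quadrant_angle
#' @return factor with levels A, R, P, L.
#' @export
quadrant_of <- function(points, center, orientation = slice_orientation()) {
  p <- as.matrix(points)
  if (length(p) == 2 && !is.matrix(points)) p <- matrix(p, ncol = 2)
  d2 <- rowSums(t(t(p) - center)^2)
  if (any(d2 == 0))
    abort("point coincides with the quadrant centre", "parameter_error")
  th <- quadrant_angle(p, center, orientation)
  idx <- floor(((th * 180 / pi + 45) %% 360) / 90)
  factor(c("A", "R", "P", "L")[idx + 1], levels = c("A", "R", "P", "L"))
}

#' Wall mask between two contours with low-magnitude exclusion
#'
#' Pixels whose centres lie between the inner and outer contour are wall
#' candidates; of these, pixels with magnitude below
#' `exclusion_fraction` times the median candidate magnitude are
#' excluded (low magnitude implies unreliable phase).
#'
#' @param inner,outer `closed_curve`s delineating the wall (inner
#'   strictly inside outer).
#' @param magnitude 2-D magnitude image (matrix, row = y index).
#' @param pixel_spacing (dx, dy) in mm (scalar recycled).
#' @param exclusion_fraction in \[0, 1); default 0.3.
#' @return logical matrix of included wall pixels.
#' @export
build_wall_mask <- function(inner, outer, magnitude, pixel_spacing,
                            exclusion_fraction = 0.3) {
  if (exclusion_fraction < 0 || exclusion_fraction >= 1)
    abort("exclusion_fraction must be in [0, 1)", "parameter_error")
  sp <- rep(pixel_spacing, length.out = 2)
  pin <- curve_points(inner, 512L)
  pout <- curve_points(outer, 512L)
  if (!all(points_in_polygon(pin, pout)))
    abort("inner contour must lie strictly inside the outer contour",
          "geometry_error")
  nr <- nrow(magnitude); nc <- ncol(magnitude)
  centers <- cbind(x = rep((seq_len(nc) - 1) * sp[1], each = nr),
                   y = rep((seq_len(nr) - 1) * sp[2], times = nc))
  between <- points_in_polygon(centers, pout) & !points_in_polygon(centers, pin)
  between <- matrix(between, nr, nc)
  if (!any(between))
    abort("no pixel centres lie between the contours", "degenerate_input_error")
  med <- stats::median(magnitude[between])
  mask <- between & (magnitude >= exclusion_fraction * med)
  if (!any(mask))
    abort("wall mask is empty after low-magnitude exclusion",
          "degenerate_input_error")
  mask
}

#' Mid-wall curve from inner and outer contours
#'
#' Samples the radius of both contours along rays from the shared
#' centroid and fits a closed spline through the mean-radius points.
#' Used when no explicit mid-wall delineation is supplied.
#'
#' @param inner,outer `closed_curve`s (star-shaped about their centroid).
#' @param n_samples number of rays.
#' @return a `closed_curve` midway between the contours.
#' @export
midwall_curve <- function(inner, outer, n_samples = 64L) {
  ctr <- (curve_centroid(inner) + curve_centroid(outer)) / 2
  ang <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
  r_in <- polygon_radius(curve_points(inner, 1024L), ctr, ang)
  r_out <- polygon_radius(curve_points(outer, 1024L), ctr, ang)
  r_mid <- (r_in + r_out) / 2
  fit_closed_curve(cbind(ctr[1] + r_mid * cos(ang), ctr[2] + r_mid * sin(ang)))
}

# radius of a star-shaped polygon from `center` along angles `ang`
# (periodic linear interpolation of vertex radii over vertex angles)
polygon_radius <- function(poly, center, ang) {
  d <- t(t(poly) - center)
  va <- atan2(d[, 2], d[, 1]) %% (2 * pi)
  vr <- sqrt(rowSums(d^2))
  o <- order(va)
  va <- va[o]; vr <- vr[o]
  va <- c(va[length(va)] - 2 * pi, va, va[1] + 2 * pi)
  vr <- c(vr[length(vr)], vr, vr[1])
  stats::approx(va, vr, xout = ang %% (2 * pi))$y
}

#' Wall delineation: inner, outer and mid-wall contours plus wall mask
#'
#' @param inner,outer closed curves (or n x 2 control-point matrices).
#' @param magnitude magnitude image used for low-magnitude exclusion.
#' @param pixel_spacing (dx, dy) mm.
#' @param mid optional explicit mid-wall curve/control points; derived
#'   as the mean-radius curve of inner and outer when absent.
#' @param exclusion_fraction low-magnitude exclusion threshold fraction.
#' @return object of class `wall_delineation` with fields `inner`,
#'   `outer`, `mid`, `mask`, `center`.
#' @export
wall_delineation <- function(inner, outer, magnitude, pixel_spacing,
                             mid = NULL, exclusion_fraction = 0.3) {
  as_curve <- function(x) if (inherits(x, "closed_curve")) x else fit_closed_curve(x)
  inner <- as_curve(inner); outer <- as_curve(outer)
  mid <- if (is.null(mid)) midwall_curve(inner, outer) else as_curve(mid)
  mask <- build_wall_mask(inner, outer, magnitude, pixel_spacing,
                          exclusion_fraction)
  structure(list(inner = inner, outer = outer, mid = mid, mask = mask,
                 center = curve_centroid(mid),
                 pixel_spacing = rep(pixel_spacing, length.out = 2)),
            class = "wall_delineation")
}

#' @export
print.wall_delineation <- function(x, ...) {
  cat(sprintf(paste0("<wall_delineation> mid-wall length %.2f mm, ",
                     "%d wall pixels, centre (%.2f, %.2f) mm\n"),
              curve_length(x$mid), sum(x$mask), x$center[1], x$center[2]))
  invisible(x)
}
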