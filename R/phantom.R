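#' Specification of a synthetic DENSE phantom
#'
#' Parametric ground truth for a deforming annular vessel wall imaged
#' with displacement encoding. The resting (diastolic) wall is the
#' annulus of mid radius `mid_radius` and thickness `wall_thickness`
#' about `center`. The forward deformation maps the resting point at
#' polar coordinates (r, theta) to radius
#' `s(theta) * mid_radius + (r - mid_radius)` at the same theta (pure
#' circumferential stretch of the mid-wall with preserved wall
#' thickness), with
#' \deqn{s(\theta) = s_0 + \sum_k a_k \cos(k\theta + \phi_k),}
#' composed with a rigid in-plane rotation about the centre, a rigid
#' in-plane translation and a constant through-plane shift. Angles here are standard image-plane
#' polar angles `atan2(y - cy, x - cx)`.
#'
#' The recorded displacement follows the acquisition timing of encoding
#' at maximal expansion and readout at rest: the per-pixel displacement
#' is `u(x) = x - F(x)` (motion from the expanded position back to the
#' resting readout position, with reversed sign), so tracking recovers
#' the expanded position as `x - u(x)`.
#'
#' Defaults emulate the acquisition geometry this pipeline targets:
#' 2.3 mm pixels, 8 mm slice, a 2.5 mm thick wall of 15 mm mid radius,
#' encoding frequency 0.08 cycles/mm.
#'
#' @param grid_size pixels per side.
#' @param pixel_spacing mm.
#' @param center (x, y) mm; default grid centre.
#' @param mid_radius mid-wall radius, mm.
#' @param wall_thickness mm.
#' @param s0 constant term of the stretch pattern.
#' @param a,phi harmonic amplitudes and phases of s(theta) (same length).
#' @param rotation rigid in-plane rotation between states, radians.
#' @param translation rigid in-plane translation between states,
#'   (dx, dy) mm.
#' @param through_plane_shift mm.
#' @param wall_magnitude,lumen_magnitude,background_magnitude signal
#'   levels (black-blood contrast requires lumen < wall).
#' @param snr ratio of wall_magnitude to complex-noise standard
#'   deviation; `Inf` for noise-free.
#' @param k_e encoding frequency, cycles/mm.
#' @param slice_thickness mm.
#' @param seed integer RNG seed; required when `snr` is finite.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64L, pixel_spacing = 2.3,
                         center = NULL, mid_radius = 15,
                         wall_thickness = 2.5,
                         s0 = 1, a = numeric(0), phi = numeric(0),
                         rotation = 0, translation = c(0, 0),
                         through_plane_shift = 0,
                         wall_magnitude = 1, lumen_magnitude = 0.05,
                         background_magnitude = 0.02,
                         snr = Inf, k_e = 0.08, slice_thickness = 8,
                         seed = NULL) {
  if (length(a) != length(phi))
    abort("a and phi must have equal length", "parameter_error")
  if (wall_thickness <= 0 || mid_radius <= wall_thickness / 2)
    abort("annulus self-intersects: need mid_radius > wall_thickness/2 > 0",
          "parameter_error")
  if (lumen_magnitude >= wall_magnitude)
    abort("black-blood contrast requires lumen_magnitude < wall_magnitude",
          "parameter_error")
  if (!is.numeric(snr) || snr <= 0)
    abort("snr must be positive (Inf allowed)", "parameter_error")
  if (is.finite(snr) && is.null(seed))
    abort("a finite snr requires an explicit seed", "configuration_error")
  if (k_e <= 0 || pixel_spacing <= 0 || grid_size < 8)
    abort("invalid geometry parameters", "parameter_error")
  if (is.null(center))
    center <- rep((grid_size - 1) / 2 * pixel_spacing, 2)
  spec <- structure(
    list(grid_size = as.integer(grid_size), pixel_spacing = pixel_spacing,
         center = center, mid_radius = mid_radius,
         wall_thickness = wall_thickness,
         s0 = s0, a = a, phi = phi, rotation = rotation,
         translation = rep(translation, length.out = 2),
         through_plane_shift = through_plane_shift,
         wall_magnitude = wall_magnitude, lumen_magnitude = lumen_magnitude,
         background_magnitude = background_magnitude,
         snr = snr, k_e = k_e, slice_thickness = slice_thickness,
         seed = seed),
    class = "phantom_spec")
  th <- seq(0, 2 * pi, length.out = 721)
  if (any(stretch_pattern(spec)(th) <= 0))
    abort("stretch pattern s(theta) must be positive everywhere",
          "parameter_error")
  spec
}

#' Angular stretch pattern s(theta) of a phantom
#' @param spec a [phantom_spec()].
#' @return function of theta (radians, standard polar angle).
#' @export
stretch_pattern <- function(spec) {
  force(spec)
  function(theta) {
    s <- rep(spec$s0, length(theta))
    for (k in seq_along(spec$a))
      s <- s + spec$a[k] * cos(k * theta + spec$phi[k])
    s
  }
}

#' Forward deformation map of a phantom
#'
#' Maps resting (x, y) positions (mm) to deformed 3-D positions.
#'
#' @param spec a [phantom_spec()].
#' @param points n x 2 matrix of resting positions (mm).
#' @return n x 3 matrix of deformed positions (z = through-plane shift).
#' @export
phantom_deform <- function(spec, points) {
  p <- as.matrix(points)
  dx <- p[, 1] - spec$center[1]
  dy <- p[, 2] - spec$center[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  s <- stretch_pattern(spec)(th)
  rnew <- s * spec$mid_radius + (r - spec$mid_radius)
  ang <- th + spec$rotation
  cbind(x = spec$center[1] + spec$translation[1] + rnew * cos(ang),
        y = spec$center[2] + spec$translation[2] + rnew * sin(ang),
        z = spec$through_plane_shift)
}

# Encoding direction metadata of the phantom's balanced 4-point scheme,
# expressed at the phase-to-displacement contract level: the reference
# acquisition carries zero net sensitivity, the other three the unit net
# directions of a symmetric tetrahedral set (differences of tetrahedron
# vertices, normalized). Rows span 3-D after reference subtraction.
balanced_directions <- function() {
  rbind(c(0, 0, 0),
        c(0, -1, -1) / sqrt(2),
        c(-1, 0, -1) / sqrt(2),
        c(-1, -1, 0) / sqrt(2))
}

#' Generate a synthetic DENSE acquisition with analytic ground truth
#'
#' Renders the resting annulus with exact partial-volume magnitude
#' (per-pixel area fraction via [circle_polygon_area()]), evaluates the
#' recorded displacement `u(x) = x - F(x)` at every pixel centre,
#' encodes it into one wrapped phase image per acquisition of a
#' balanced tetrahedral 4-point set (phase
#' \eqn{2\pi k_e\, d_a \cdot u}, reference phase zero), and applies
#' complex Gaussian noise at the requested SNR to the complex signal of
#' every acquisition before extracting magnitude and phase.
#'
#' @param spec a [phantom_spec()].
#' @param exclusion_fraction low-magnitude exclusion used for the
#'   bundled wall delineation.
#' @return list of class `dense_phantom` with elements
#'   `acquisition` ([dense_acquisition()]), `truth` (exact displacement
#'   array `u`, the deformation map, the true stretch profile function
#'   and true contours in both states) and `delineation`
#'   ([wall_delineation()] built from the true resting contours).
#' @export
make_phantom <- function(spec, exclusion_fraction = 0.3) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  sp <- spec$pixel_spacing
  xs <- (seq_len(n) - 1) * sp
  centers <- cbind(x = rep(xs, each = n), y = rep(xs, times = n))

  r_in <- spec$mid_radius - spec$wall_thickness / 2
  r_out <- spec$mid_radius + spec$wall_thickness / 2
  f_out <- circle_cover_fraction(spec$center, r_out, centers, sp)
  f_in <- circle_cover_fraction(spec$center, r_in, centers, sp)
  mag0 <- spec$wall_magnitude * (f_out - f_in) +
    spec$lumen_magnitude * f_in +
    spec$background_magnitude * (1 - f_out)
  mag0 <- matrix(mag0, n, n)

  u <- centers_displacement(spec, centers)           # npix x 3
  D <- balanced_directions()
  phase_true <- lapply(seq_len(nrow(D)), function(a) {
    if (a == 1) matrix(0, n, n)                      # reference phase zero
    else matrix(wrap_phase(2 * pi * spec$k_e * (u %*% D[a, ])), n, n)
  })
  # acquisition a = 1 is the designated reference; its *net* direction
  # rows (d_a - d_1) span 3-D
  phases <- phase_true
  magnitude <- mag0
  if (is.finite(spec$snr)) {
    sigma <- spec$wall_magnitude / spec$snr
    res <- with_seed(spec$seed, {
      lapply(seq_along(phases), function(a) {
        z <- mag0 * exp(1i * phase_true[[a]]) +
          sigma * (matrix(stats::rnorm(n * n), n, n) +
                     1i * matrix(stats::rnorm(n * n), n, n))
        z
      })
    })
    phases <- lapply(res, function(z) {
      p <- Arg(z); p[p <= -pi] <- pi; p
    })
    magnitude <- Mod(res[[1]])
  }
  acq <- dense_acquisition(magnitude, phases, D, k_e = spec$k_e,
                           pixel_spacing = sp,
                           slice_thickness = spec$slice_thickness,
                           reference = 1L)

  uarr <- array(NA_real_, c(n, n, 3))
  for (comp in 1:3) uarr[, , comp] <- matrix(u[, comp], n, n)

  circ <- function(radius, deformed = FALSE) {
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    p <- cbind(spec$center[1] + radius * cos(th),
               spec$center[2] + radius * sin(th))
    if (deformed) p <- phantom_deform(spec, p)[, 1:2]
    fit_closed_curve(p)
  }
  truth <- list(
    displacement = uarr,
    deform = function(points) phantom_deform(spec, points),
    stretch_of_theta = function(theta) analytic_stretch_profile(spec, theta),
    contours = list(
      rest = list(inner = circ(r_in), outer = circ(r_out),
                  mid = circ(spec$mid_radius)),
      deformed = list(inner = circ(r_in, TRUE), outer = circ(r_out, TRUE),
                      mid = circ(spec$mid_radius, TRUE))))

  delin <- wall_delineation(truth$contours$rest$inner,
                            truth$contours$rest$outer,
                            magnitude = magnitude, pixel_spacing = sp,
                            mid = truth$contours$rest$mid,
                            exclusion_fraction = exclusion_fraction)
  structure(list(acquisition = acq, truth = truth, delineation = delin,
                 spec = spec),
            class = "dense_phantom")
}

# per-pixel recorded displacement u(x) = x - F(x), npix x 3
centers_displacement <- function(spec, centers) {
  Fp <- phantom_deform(spec, centers)
  cbind(centers[, 1] - Fp[, 1], centers[, 2] - Fp[, 2], -Fp[, 3])
}

# exact covered-area fraction of each square pixel by the disk
circle_cover_fraction <- function(center, radius, pixel_centers, sp) {
  d <- sqrt((pixel_centers[, 1] - center[1])^2 +
              (pixel_centers[, 2] - center[2])^2)
  half_diag <- sp * sqrt(2) / 2
  frac <- as.numeric(d <= radius - half_diag)    # fully inside
  edge <- which(d > radius - half_diag & d < radius + half_diag)
  for (i in edge) {
    cx <- pixel_centers[i, 1]; cy <- pixel_centers[i, 2]
    rect <- cbind(cx + c(-1, 1, 1, -1) * sp / 2,
                  cy + c(-1, -1, 1, 1) * sp / 2)
    frac[i] <- circle_polygon_area(center[1], center[2], radius, rect) / sp^2
  }
  frac
}

#' True circumferential stretch of the phantom at given angles
#'
#' Ratio of deformed to resting arc-length density of the mid-wall
#' curve, \eqn{|dC_{sys}/d\theta| / |dC_{dia}/d\theta|}, evaluated by
#' central-difference numerical differentiation of the deformed
#' mid-wall curve with automatic step refinement (halving the step
#' until the result changes by less than 1e-8).
#'
#' @param spec a [phantom_spec()].
#' @param thetas angles (radians, standard polar angle at rest).
#' @return stretch ratios at `thetas`.
#' @export
analytic_stretch_profile <- function(spec, thetas) {
  stopifnot(inherits(spec, "phantom_spec"))
  mid_point <- function(th) {
    cbind(spec$center[1] + spec$mid_radius * cos(th),
          spec$center[2] + spec$mid_radius * sin(th))
  }
  deriv_norm <- function(th, h) {
    a <- phantom_deform(spec, mid_point(th + h))
    b <- phantom_deform(spec, mid_point(th - h))
    sqrt(rowSums((a - b)^2)) / (2 * h)
  }
  h <- 1e-3
  cur <- deriv_norm(thetas, h)
  repeat {
    h <- h / 2
    nxt <- deriv_norm(thetas, h)
    if (max(abs(nxt - cur)) < 1e-8 || h < 1e-7) break
    cur <- nxt
  }
  nxt / spec$mid_radius
}

#' Synthetic cine lumen-contour series
#'
#' Interpolates the lumen contour between the resting and fully
#' deformed states with a smooth cyclic weighting
#' \eqn{w_j = (1 - \cos(2\pi j / n))/2}, so the first frame is the
#' resting (minimum-area) state and the mid-cycle frame the fully
#' deformed (maximum-area) state. The cine lumen deforms homothetically
#' with the stretch pattern (vertex radius scaled by s(theta)), so for a
#' uniform scaling `s0` the lumen area scales exactly by `s0^2`.
#'
#' @param spec a [phantom_spec()].
#' @param n_frames number of frames (>= 2).
#' @param seed optional seed for vertex jitter.
#' @param jitter_sd contour-vertex jitter standard deviation (mm).
#' @param n_vertices polygon vertices per frame.
#' @return object of class `area_series`: list of polygons and areas.
#' @export
make_cine_series <- function(spec, n_frames, seed = NULL, jitter_sd = 0,
                             n_vertices = 100L) {
  if (n_frames < 2) abort("n_frames must be >= 2", "parameter_error")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r0 <- spec$mid_radius - spec$wall_thickness / 2
  s <- stretch_pattern(spec)(th)
  rest <- cbind(spec$center[1] + r0 * cos(th),
                spec$center[2] + r0 * sin(th))
  ang <- th + spec$rotation
  def <- cbind(spec$center[1] + spec$translation[1] + s * r0 * cos(ang),
               spec$center[2] + spec$translation[2] + s * r0 * sin(ang))
  w <- (1 - cos(2 * pi * (seq_len(n_frames) - 1) / n_frames)) / 2
  polys <- lapply(w, function(wi) (1 - wi) * rest + wi * def)
  if (jitter_sd > 0) {
    if (is.null(seed)) abort("vertex jitter requires a seed", "configuration_error")
    polys <- with_seed(seed, lapply(polys, function(p)
      p + matrix(stats::rnorm(length(p), sd = jitter_sd), ncol = 2)))
  }
  structure(list(polygons = polys,
                 areas = vapply(polys, polygon_area, numeric(1))),
            class = "area_series")
}

#' @export
print.dense_phantom <- function(x, ...) {
  cat(sprintf(paste0("<dense_phantom> %d x %d grid, s0 = %g, %d harmonics, ",
                     "rotation %.3f rad, shift %g mm, snr = %g\n"),
              x$spec$grid_size, x$spec$grid_size, x$spec$s0,
              length(x$spec$a), x$spec$rotation,
              x$spec$through_plane_shift, x$spec$snr))
  invisible(x)
}
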