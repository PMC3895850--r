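#' Seed equidistant points along the mid-wall delineation
#'
#' Distributes `n` points at equal arc-length spacing along a closed
#' curve, starting where the curve crosses the anterior (A) axis and
#' proceeding in the direction of increasing circumferential angle
#' (A towards R).
#'
#' @param mid a `closed_curve` (arc-length parameterized).
#' @param n number of points (>= 8; default 100).
#' @param center angular reference centre; defaults to the curve
#'   centroid.
#' @param orientation a [slice_orientation()].
#' @return n x 2 matrix of points (mm), attribute `"u"` holding the
#'   curve parameters.
#' @export
seed_points <- function(mid, n = 100L, center = NULL,
                        orientation = slice_orientation()) {
  if (n < 8) abort("n must be >= 8", "parameter_error")
  if (is.null(center)) center <- curve_centroid(mid)

  # find the A-axis crossing: theta(u) = 0 with theta measured from A
  m <- 2048L
  ug <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
  th <- quadrant_angle(curve_eval(mid, ug), center, orientation)
  i0 <- which.min(pmin(th, 2 * pi - th))
  f <- function(u) {
    t <- quadrant_angle(curve_eval(mid, u), center, orientation)
    ifelse(t > pi, t - 2 * pi, t)           # signed angle near zero
  }
  lo <- ug[i0] - 1.5 / m; hi <- ug[i0] + 1.5 / m
  u0 <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                 error = function(e) ug[i0])

  # traversal direction: quadrant angle must increase along the curve
  dir <- if (f(u0 + 1e-4) > f(u0 - 1e-4)) 1 else -1
  u <- (u0 + dir * (seq_len(n) - 1) / n) %% 1
  pts <- curve_eval(mid, u)
  attr(pts, "u") <- u
  pts
}

# Keys bicubic kernel, a = -1/2
keys_kernel <- function(s) {
  s <- abs(s)
  out <- numeric(length(s))
  i <- s < 1
  out[i] <- 1.5 * s[i]^3 - 2.5 * s[i]^2 + 1
  j <- s >= 1 & s < 2
  out[j] <- -0.5 * s[j]^3 + 2.5 * s[j]^2 - 4 * s[j] + 2
  out
}

# certainty-aware bicubic sampling of one displacement component.
# Invalid / zero-certainty footprint pixels are excluded and the Keys
# weights renormalized over the remaining ones.
sample_bicubic <- function(comp, valid, x_px, y_px) {
  nr <- nrow(comp); nc <- ncol(comp)
  j0 <- floor(x_px); i0 <- floor(y_px)
  vals <- 0; wsum <- 0
  for (dj in -1:2) for (di in -1:2) {
    jj <- j0 + dj; ii <- i0 + di
    w <- keys_kernel(x_px - jj) * keys_kernel(y_px - ii)
    inb <- jj >= 0 & jj < nc & ii >= 0 & ii < nr
    idx <- cbind(pmax(pmin(ii, nr - 1), 0) + 1, pmax(pmin(jj, nc - 1), 0) + 1)
    ok <- inb & valid[idx]
    v <- comp[idx]
    v[!ok] <- 0
    w[!ok] <- 0
    vals <- vals + w * v
    wsum <- wsum + w
  }
  ifelse(wsum == 0, NA_real_, vals / wsum)
}

#' Track mid-wall points through the displacement field
#'
#' Samples each displacement component at the sub-pixel point locations
#' by certainty-weighted bicubic interpolation (invalid footprint pixels
#' excluded, weights renormalized) and recovers the expanded (systolic)
#' position as `diastolic - u`: the encoded displacement carries tissue
#' from the expanded state to the resting readout state, so the
#' expanded position is found by subtraction. The through-plane
#' component becomes the z coordinate of the systolic points.
#'
#' @param points n x 2 matrix of diastolic positions on the mid-wall
#'   (mm).
#' @param field a [displacement_field()].
#' @return object of class `tracked_points`: list with `diastolic`
#'   (n x 3, z = 0) and `systolic` (n x 3) matrices.
#' @export
track_points <- function(points, field) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  sp <- field$pixel_spacing
  x_px <- p[, 1] / sp[1]
  y_px <- p[, 2] / sp[2]
  u <- sapply(1:3, function(comp)
    sample_bicubic(field$u[, , comp], field$valid, x_px, y_px))
  if (any(!is.finite(u))) {
    bad <- which(apply(!is.finite(u), 1, any))
    abort(paste0("no valid displacement support at point(s) ",
                 paste(bad, collapse = ", ")), "tracking_error")
  }
  dia <- cbind(p, 0)
  sys <- cbind(p[, 1] - u[, 1], p[, 2] - u[, 2], -u[, 3])
  colnames(dia) <- colnames(sys) <- c("x", "y", "z")
  structure(list(diastolic = dia, systolic = sys, n = nrow(p)),
            class = "tracked_points")
}

#' Circumferential stretch profile from tracked points
#'
#' Both point sets are regularized with a `pieces`-piece periodic
#' least-squares cubic spline (fitted per coordinate against the point
#' index) and projected onto their splines at the nearest parameter.
#' The per-segment stretch is the ratio of distances between adjacent
#' projected points along the expanded and resting state splines,
#' \deqn{\lambda_i = \|P_{sys,i+1} - P_{sys,i}\|_{3D} /
#'       \|P_{dia,i+1} - P_{dia,i}\|_{2D},}
#' with systolic distances taken in 3-D (through-plane motion included)
#' and diastolic distances in the imaging plane. Applying the identical
#' spline treatment to both states makes the profile exactly 1 under
#' identity and rigid motions: spline fitting and projection commute
#' with rigid maps, so the spline's small approximation ripple cancels
#' in the ratio.
#'
#' @param tracked a [track_points()] result.
#' @param pieces spline pieces (default 5).
#' @param center angular reference centre; defaults to the diastolic
#'   point centroid.
#' @param orientation a [slice_orientation()].
#' @param mode "chord" (default) for straight-line distances between
#'   projected points, "arc" for arc lengths along the splines.
#' @return object of class `stretch_profile`: data frame with one row
#'   per segment: `lambda`, `theta` (segment mid-angle, radians from
#'   the A axis), `quadrant`.
#' @export
stretch_profile <- function(tracked, pieces = 5L, center = NULL,
                            orientation = slice_orientation(),
                            mode = c("chord", "arc")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tracked, "tracked_points"))
  n <- tracked$n
  dia2 <- tracked$diastolic[, 1:2, drop = FALSE]
  if (is.null(center)) center <- colMeans(dia2)

  sp_dia <- fit_periodic_spline(dia2, pieces)
  sp_sys <- fit_periodic_spline(tracked$systolic, pieces)
  pr_dia <- project_onto_curve(sp_dia, dia2, window = 2 / pieces / 4)
  pr_sys <- project_onto_curve(sp_sys, tracked$systolic,
                               window = 2 / pieces / 4)

  nxt <- c(2:n, 1)
  if (mode == "chord") {
    len_dia <- sqrt(rowSums((pr_dia$points[nxt, , drop = FALSE] -
                               pr_dia$points)^2))
    len_sys <- sqrt(rowSums((pr_sys$points[nxt, , drop = FALSE] -
                               pr_sys$points)^2))
  } else {
    len_dia <- spline_arc_lengths(sp_dia, pr_dia$t)
    len_sys <- spline_arc_lengths(sp_sys, pr_sys$t)
  }
  if (any(len_dia <= 0))
    abort("zero-length diastolic segment", "degenerate_input_error")
  lambda <- len_sys / len_dia

  mids <- (dia2 + dia2[nxt, , drop = FALSE]) / 2
  theta <- quadrant_angle(mids, center, orientation)
  quad <- quadrant_of(mids, center, orientation)
  structure(data.frame(segment = seq_len(n), lambda = lambda,
                       theta = theta, quadrant = quad),
            class = c("stretch_profile", "data.frame"))
}

# arc length along a bspline_curve between consecutive parameters
# (16-point Gauss-Legendre per segment)
spline_arc_lengths <- function(curve, t) {
  n <- length(t)
  gx <- c(-0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
          -0.755404408355003, -0.6178762444026438, -0.45801677765722737,
          -0.2816035507792589, -0.09501250983763744, 0.09501250983763744,
          0.2816035507792589, 0.45801677765722737, 0.6178762444026438,
          0.755404408355003, 0.8656312023878318, 0.9445750230732326,
          0.9894009349916499)
  gw <- c(0.027152459411754095, 0.0622535239386479, 0.09515851168249278,
          0.12462897125553387, 0.14959598881657673, 0.16915651939500254,
          0.18260341504492358, 0.1894506104550685, 0.1894506104550685,
          0.18260341504492358, 0.16915651939500254, 0.14959598881657673,
          0.12462897125553387, 0.09515851168249278, 0.0622535239386479,
          0.027152459411754095)
  t2 <- c(t[-1], t[1] + 1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- t[i]; b <- if (t2[i] > t[i]) t2[i] else t2[i] + 1
    tt <- (a + b) / 2 + (b - a) / 2 * gx
    d <- curve_eval(curve, tt, deriv = 1L)
    out[i] <- (b - a) / 2 * sum(gw * sqrt(rowSums(d^2)))
  }
  out
}

#' Quadrant summary of a stretch profile
#'
#' Overall and per-quadrant mean stretch plus the relative stretch
#' difference per quadrant,
#' \deqn{(S_{quadrant} - S_{overall}) / S_{overall},}
#' the asymmetry statistic of the quadrant analysis.
#'
#' @param profile a [stretch_profile()].
#' @return object of class `quadrant_summary` with `s_overall`,
#'   `s_quadrant` (named A/R/P/L), `rel_diff`, `percent` (stretch as
#'   percentage, ratio x 100) and `n_segments` per quadrant.
#' @export
quadrant_summary <- function(profile) {
  counts <- table(profile$quadrant)
  if (any(counts == 0))
    abort(paste0("empty quadrant(s): ",
                 paste(names(counts)[counts == 0], collapse = ", ")),
          "analysis_error")
  s_overall <- mean(profile$lambda)
  s_quadrant <- tapply(profile$lambda, profile$quadrant, mean)
  rel_diff <- (s_quadrant - s_overall) / s_overall
  structure(list(s_overall = s_overall,
                 s_quadrant = s_quadrant,
                 rel_diff = rel_diff,
                 percent = c(overall = s_overall * 100, s_quadrant * 100),
                 n_segments = as.vector(counts)),
            class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("<quadrant_summary> overall stretch %.4f (%.1f%%)\n",
              x$s_overall, 100 * x$s_overall))
  for (q in names(x$s_quadrant))
    cat(sprintf("  %s: stretch %.4f, relative difference %+.4f\n",
                q, x$s_quadrant[[q]], x$rel_diff[[q]]))
  invisible(x)
}

#' @export
print.stretch_profile <- function(x, ...) {
  cat(sprintf("<stretch_profile> %d segments, mean lambda %.4f (range %.4f-%.4f)\n",
              nrow(x), mean(x$lambda), min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Plot a circumferential stretch profile
#'
#' Stretch ratio against circumferential angle, with quadrant
#' boundaries marked.
#'
#' @param x a [stretch_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.stretch_profile <- function(x, ...) {
  graphics::plot(x$theta * 180 / pi, x$lambda, type = "p", pch = 16,
                 cex = 0.6, xlab = "angle from anterior axis (degrees)",
                 ylab = "stretch ratio", ...)
  graphics::abline(v = c(45, 135, 225, 315), lty = 3, col = "grey50")
  graphics::abline(h = 1, lty = 2, col = "grey70")
  mids <- c(0, 90, 180, 270)
  graphics::mtext(c("A", "R", "P", "L"), side = 3, at = mids, line = 0.2)
  invisible(x)
}
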