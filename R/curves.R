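#' Closed periodic curves
#'
#' Two families of closed curves are used throughout the pipeline:
#'
#' * `interp_curve` — a periodic cubic *interpolating* spline through
#'   operator-supplied control points, reparameterized by arc length
#'   (equal parameter steps correspond to equal arc length to well below
#'   0.1%). Produced by [fit_closed_curve()]; this is the wall
#'   delineation primitive.
#' * `bspline_curve` — a periodic uniform cubic B-spline fitted by least
#'   squares with a small number of pieces, used to regularize tracked
#'   point sets ([fit_periodic_spline()]).
#'
#' Both inherit from class `closed_curve` and support [curve_eval()].
#'
#' @name closed_curves
NULL

#' Fit a closed periodic interpolating spline through control points
#'
#' Builds a C1-continuous closed cubic spline through the given points
#' (periodic end conditions, chord-length parameterization) and
#' reparameterizes it so that the curve parameter is arc-length fraction:
#' `curve_eval(curve, u)` with `u` in \[0, 1) advances at constant speed.
#'
#' @param control_points numeric matrix (n x 2) of ordered (x, y)
#'   positions in mm; at least 4 distinct points; the curve closes from
#'   the last point back to the first.
#' @return an object of class `c("interp_curve", "closed_curve")`.
#' @seealso [curve_eval()], [curve_length()], [fit_periodic_spline()]
#' @export
fit_closed_curve <- function(control_points) {
  p <- as.matrix(control_points)
  if (!is.numeric(p) || ncol(p) != 2)
    abort("control points must be an n x 2 numeric matrix", "parameter_error")
  if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 4)
    abort("a closed curve needs at least 4 distinct control points", "validation_error")
  dup <- rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2) == 0
  if (any(dup))
    abort("duplicated consecutive control points", "validation_error")

  n <- nrow(p)
  ch <- sqrt(rowSums((p[c(2:n, 1), , drop = FALSE] - p)^2))
  t <- c(0, cumsum(ch)) / sum(ch)          # length n + 1, t[n+1] = 1
  xs <- c(p[, 1], p[1, 1])
  ys <- c(p[, 2], p[1, 2])
  fx <- stats::splinefun(t, xs, method = "periodic")
  fy <- stats::splinefun(t, ys, method = "periodic")

  # arc-length reparameterization on a fine grid
  m <- 4096L
  tg <- seq(0, 1, length.out = m + 1L)
  sp <- sqrt(fx(tg, deriv = 1)^2 + fy(tg, deriv = 1)^2)
  seg <- (sp[-1] + sp[-(m + 1L)]) / 2 / m  # trapezoid per cell
  cum <- c(0, cumsum(seg))
  len <- cum[m + 1L]
  if (len <= 0) abort("degenerate curve of zero length", "geometry_error")
  arcfrac <- cum / len
  tinv <- stats::splinefun(arcfrac, tg, method = "hyman")

  curve <- structure(
    list(fx = fx, fy = fy, tinv = tinv, length = len,
         control_points = p),
    class = c("interp_curve", "closed_curve"))

  poly <- curve_points(curve, 512L)
  if (polygon_self_intersects(poly))
    abort("fitted closed curve self-intersects", "geometry_error")
  curve
}

#' Evaluate a closed curve
#'
#' @param curve a `closed_curve`.
#' @param u parameter values; arc-length fraction for `interp_curve`,
#'   periodic fit parameter for `bspline_curve`. Taken modulo 1.
#' @param deriv 0 for position, 1 for the derivative with respect to `u`.
#' @return numeric matrix, one row per value of `u`.
#' @export
curve_eval <- function(curve, u, deriv = 0L) UseMethod("curve_eval")

#' @export
curve_eval.interp_curve <- function(curve, u, deriv = 0L) {
  u <- u %% 1
  t <- curve$tinv(u)
  if (deriv == 0L) {
    cbind(x = curve$fx(t), y = curve$fy(t))
  } else {
    dx <- curve$fx(t, deriv = 1); dy <- curve$fy(t, deriv = 1)
    sp <- sqrt(dx^2 + dy^2)
    cbind(x = dx, y = dy) * (curve$length / sp)
  }
}

#' Total arc length of a closed curve (mm)
#' @param curve a `closed_curve`.
#' @export
curve_length <- function(curve) UseMethod("curve_length")

#' @export
curve_length.interp_curve <- function(curve) curve$length

#' @export
curve_length.bspline_curve <- function(curve) {
  tg <- seq(0, 1, length.out = 4097L)
  p <- curve_eval(curve, tg)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Polygonize a closed curve
#' @param curve a `closed_curve`.
#' @param n number of vertices.
#' @return n x d matrix of points at equal parameter steps.
#' @export
curve_points <- function(curve, n = 512L) {
  curve_eval(curve, seq(0, 1, length.out = n + 1L)[-(n + 1L)])
}

#' Centroid of a closed curve (vertex mean of a fine polygonization)
#' @param curve a `closed_curve`.
#' @export
curve_centroid <- function(curve) {
  colMeans(curve_points(curve, 1024L))[1:2]
}

#' @export
print.closed_curve <- function(x, ...) {
  p <- curve_points(x, 256L)
  cat(sprintf("<%s> length %.3f mm, centroid (%.2f, %.2f) mm\n",
              class(x)[1], curve_length(x), mean(p[, 1]), mean(p[, 2])))
  invisible(x)
}

## ---- periodic uniform cubic B-splines ------------------------------------

# cardinal cubic B-spline on support [0, 4]
bspline3 <- function(x) {
  r <- numeric(length(x))
  i <- x >= 0 & x < 1; xi <- x[i];      r[i] <- xi^3 / 6
  i <- x >= 1 & x < 2; xi <- x[i] - 1;  r[i] <- (1 + 3 * xi + 3 * xi^2 - 3 * xi^3) / 6
  i <- x >= 2 & x < 3; xi <- x[i] - 2;  r[i] <- (4 - 6 * xi^2 + 3 * xi^3) / 6
  i <- x >= 3 & x < 4; xi <- x[i] - 3;  r[i] <- (1 - xi)^3 / 6
  r
}

bspline3_deriv <- function(x) {
  r <- numeric(length(x))
  i <- x >= 0 & x < 1; xi <- x[i];      r[i] <- xi^2 / 2
  i <- x >= 1 & x < 2; xi <- x[i] - 1;  r[i] <- (3 + 6 * xi - 9 * xi^2) / 6
  i <- x >= 2 & x < 3; xi <- x[i] - 2;  r[i] <- (-12 * xi + 9 * xi^2) / 6
  i <- x >= 3 & x < 4; xi <- x[i] - 3;  r[i] <- -(1 - xi)^2 / 2
  r
}

# design matrix of the K-piece periodic cubic B-spline basis at t in [0, 1)
periodic_bspline_basis <- function(t, pieces, deriv = 0L) {
  K <- as.integer(pieces)
  t <- t %% 1
  B <- matrix(0, length(t), K)
  f <- if (deriv == 0L) bspline3 else bspline3_deriv
  shifts <- K * (-2:2)
  for (j in 0:(K - 1L)) {
    acc <- 0
    for (s in shifts) acc <- acc + f(t * K - j + 2 + s)
    B[, j + 1L] <- acc
  }
  if (deriv == 1L) B <- B * K
  B
}

#' Least-squares periodic cubic B-spline through ordered periodic points
#'
#' Fits, per coordinate, a periodic uniform cubic B-spline with `pieces`
#' knot intervals to the point sequence, parameterized by index fraction
#' `(i - 1) / n`. This is the noise-regularization step applied to
#' tracked wall points before stretch is measured.
#'
#' @param points numeric matrix (n x d) of ordered points on a closed
#'   loop (d = 2 or 3); `n >= 2 * pieces`.
#' @param pieces number of spline pieces (knot intervals); default 5.
#' @return object of class `c("bspline_curve", "closed_curve")`.
#' @export
fit_periodic_spline <- function(points, pieces = 5L) {
  p <- as.matrix(points)
  K <- as.integer(pieces)
  if (K < 3L) abort("pieces must be >= 3", "parameter_error")
  if (nrow(p) < 2L * K)
    abort(sprintf("need at least %d points for %d pieces", 2L * K, K),
          "parameter_error")
  t <- (seq_len(nrow(p)) - 1) / nrow(p)
  B <- periodic_bspline_basis(t, K)
  coef <- qr.solve(B, p)
  structure(list(coef = coef, pieces = K, n_points = nrow(p)),
            class = c("bspline_curve", "closed_curve"))
}

#' @export
curve_eval.bspline_curve <- function(curve, u, deriv = 0L) {
  B <- periodic_bspline_basis(u, curve$pieces, deriv = deriv)
  B %*% curve$coef
}

#' Nearest-parameter projection of points onto a closed curve
#'
#' For each point, finds the curve parameter minimizing the Euclidean
#' distance, searching near a supplied initial parameter (points tracked
#' in order stay in order).
#'
#' @param curve a `closed_curve`.
#' @param points n x d matrix.
#' @param t_init initial parameter guesses (length n); defaults to
#'   `(i - 1) / n`.
#' @param window half-width of the parameter search interval.
#' @return list with `t` (parameters mod 1) and `points` (projections).
#' @export
project_onto_curve <- function(curve, points, t_init = NULL, window = 0.05) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (is.null(t_init)) t_init <- (seq_len(n) - 1) / n
  tt <- numeric(n)
  for (i in seq_len(n)) {
    f <- function(s) sum((curve_eval(curve, s)[1, ] - p[i, ])^2)
    tt[i] <- stats::optimize(f, c(t_init[i] - window, t_init[i] + window),
                             tol = 1e-10)$minimum %% 1
  }
  list(t = tt, points = curve_eval(curve, tt))
}
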