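#' Wrap phase values into (-pi, pi]
#'
#' Reduces arbitrary phase values modulo \eqn{2\pi} into the principal
#' interval \eqn{(-\pi, \pi]}, the storage convention used for all wrapped
#' phase images in this package.
#'
#' @param x numeric vector, matrix or array of phase values (radians).
#' @return object of the same shape with values in \eqn{(-\pi, \pi]}.
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Weighted median
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @return the smallest `x` at which the cumulative weight reaches half the
#'   total weight.
#' @keywords internal
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  keep <- w > 0 & is.finite(x)
  if (!any(keep)) stop("weighted_median: no positive-weight finite values")
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= cw[length(cw)] / 2)[1]]
}

# stop() with a classed condition so callers/tests can distinguish
# validation failures from computation failures.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "aortastretch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Area of intersection between a disk and a simple polygon
#'
#' Exact (closed-form) intersection area between the disk of radius `r`
#' centred at `(cx, cy)` and the polygon with vertex matrix `poly`
#' (n x 2, in order, implicitly closed). Used for the phantom's
#' partial-volume rendering of the annular wall.
#'
#' Each directed polygon edge contributes a Green's-theorem term: segment
#' portions inside the disk contribute the triangle area spanned with the
#' disk centre, portions outside contribute the circular-sector area
#' subtended by their endpoints.
#'
#' @param cx,cy disk centre (mm).
#' @param r disk radius (mm).
#' @param poly numeric matrix (n x 2) of polygon vertices (mm).
#' @return intersection area (mm^2), non-negative.
#' @export
circle_polygon_area <- function(cx, cy, r, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3, r >= 0)
  if (r == 0) return(0)
  p <- sweep(poly, 2, c(cx, cy))
  n <- nrow(p)
  total <- 0
  for (i in seq_len(n)) {
    a <- p[i, ]
    b <- p[if (i == n) 1L else i + 1L, ]
    d <- b - a
    dd <- sum(d * d)
    if (dd == 0) next
    # |a + t d|^2 = r^2  ->  dd t^2 + 2 (a.d) t + |a|^2 - r^2 = 0
    ad <- sum(a * d)
    disc <- ad * ad - dd * (sum(a * a) - r * r)
    ts <- c(0, 1)
    if (disc > 0) {
      sq <- sqrt(disc)
      t1 <- (-ad - sq) / dd
      t2 <- (-ad + sq) / dd
      ts <- sort(unique(c(0, 1, pmax(0, pmin(1, c(t1, t2))))))
    }
    for (k in seq_len(length(ts) - 1)) {
      t0 <- ts[k]; t1 <- ts[k + 1]
      if (t1 <= t0) next
      pm <- a + (t0 + t1) / 2 * d
      pa <- a + t0 * d
      pb <- a + t1 * d
      if (sum(pm * pm) <= r * r) {
        total <- total + (pa[1] * pb[2] - pa[2] * pb[1]) / 2
      } else {
        dang <- atan2(pb[2], pb[1]) - atan2(pa[2], pa[1])
        dang <- dang - 2 * pi * round(dang / (2 * pi))
        total <- total + r * r / 2 * dang
      }
    }
  }
  abs(total)
}

# Vectorized even-odd point-in-polygon via mgcv::in.out on a closed
# polygon given as an n x 2 matrix (not repeated at the end).
points_in_polygon <- function(points, poly) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, as.matrix(points))
}

# TRUE if any two non-adjacent segments of the closed polyline intersect.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  # test all segment pairs (i, j), j > i + 1, excluding the (1, n) adjacency
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  ij <- ij[ij[, 2] - ij[, 1] > 1 & !(ij[, 1] == 1 & ij[, 2] == n), , drop = FALSE]
  if (nrow(ij) == 0) return(FALSE)
  p1 <- a[ij[, 1], , drop = FALSE]; p2 <- b[ij[, 1], , drop = FALSE]
  p3 <- a[ij[, 2], , drop = FALSE]; p4 <- b[ij[, 2], , drop = FALSE]
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  dp <- p3 - p1
  t <- (dp[, 1] * d2[, 2] - dp[, 2] * d2[, 1]) / denom
  s <- (dp[, 1] * d1[, 2] - dp[, 2] * d1[, 1]) / denom
  hit <- is.finite(t) & is.finite(s) & t > 0 & t < 1 & s > 0 & s < 1
  any(hit)
}

# Evaluate a function under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
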