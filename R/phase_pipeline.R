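## ---- discrete cosine transforms (FFT-based) ------------------------------

# unnormalized DCT-II of each column: X_k = 2 * sum_n x_n cos(pi k (2n+1) / (2N))
dct2_cols <- function(x) {
  N <- nrow(x)
  v <- x[c(seq(1, N, 2), rev(seq(2, N, 2))), , drop = FALSE]
  F <- stats::mvfft(v)
  ph <- exp(-1i * pi * (0:(N - 1)) / (2 * N))
  Re(ph * F) * 2
}

dct2d <- function(m) t(dct2_cols(t(dct2_cols(m))))

# DCT-III (inverse of DCT-II up to 1/(2N)): x_n = (X_0/2 + sum_k X_k cos(...)) / N
idct_cols <- function(X) {
  N <- nrow(X)
  ph <- exp(1i * pi * (0:(N - 1)) / (2 * N)) / 2
  Xc <- X * 0i
  # build complex spectrum: W_k = ph_k * (X_k - i X_{N-k}), with X_N := 0
  Xrev <- rbind(0, X[N:2, , drop = FALSE])
  W <- ph * (X - 1i * Xrev)
  v <- Re(stats::mvfft(W, inverse = TRUE)) / N
  out <- matrix(0, N, ncol(X))
  out[seq(1, N, 2), ] <- v[1:ceiling(N / 2), , drop = FALSE]
  out[rev(seq(2, N, 2)), ] <- v[(ceiling(N / 2) + 1):N, , drop = FALSE]
  out
}

idct2d <- function(m) t(idct_cols(t(idct_cols(m))))

## ---- normalized averaging ------------------------------------------------

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable zero-padded convolution of matrix M with 1-D kernel k
conv_separable <- function(M, k) {
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(A) {
    n <- nrow(A)
    P <- rbind(matrix(0, r, ncol(A)), A, matrix(0, r, ncol(A)))
    out <- matrix(0, n, ncol(A))
    for (j in seq_along(k)) out <- out + k[j] * P[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(M))))
}

#' Certainty-weighted normalized averaging of a wrapped phase image
#'
#' Smooths wrapped phase by normalized convolution of its unit-complex
#' representation: `arg( G_sigma * (c e^{i phi}) / G_sigma * c )`, where
#' `c` is the per-pixel certainty (typically the signal magnitude,
#' zeroed outside the wall mask) and `G_sigma` a Gaussian of standard
#' deviation `sigma_px` pixels. Working on `e^{i phi}` makes the
#' operation respect phase wraps; weighting by certainty lets unreliable
#' pixels borrow phase from reliable neighbours.
#'
#' Pixels where the smoothed certainty falls below
#' `floor_frac * max(G_sigma * c)` have no usable support and are
#' flagged invalid.
#'
#' @param phase wrapped phase matrix, values in (-pi, pi].
#' @param certainty non-negative certainty matrix, same shape.
#' @param sigma_px Gaussian standard deviation in pixel widths
#'   (default 1).
#' @param floor_frac support floor as a fraction of the maximum smoothed
#'   certainty.
#' @return list with `phase` (wrapped, smoothed), `valid` (logical
#'   matrix) and `support` (the smoothed certainty).
#' @export
normalized_average <- function(phase, certainty, sigma_px = 1,
                               floor_frac = 1e-3) {
  if (sigma_px <= 0) abort("sigma_px must be positive", "parameter_error")
  if (!all(dim(phase) == dim(certainty)))
    abort("phase and certainty must share one shape", "validation_error")
  if (any(certainty < 0)) abort("certainty must be non-negative", "validation_error")
  if (all(certainty == 0))
    abort("certainty is zero everywhere", "degenerate_input_error")
  k <- gaussian_kernel_1d(sigma_px)
  zr <- conv_separable(certainty * cos(phase), k)
  zi <- conv_separable(certainty * sin(phase), k)
  den <- conv_separable(certainty, k)
  valid <- den > floor_frac * max(den)
  out <- atan2(zi, zr)
  out[out <= -pi] <- pi
  out[!valid] <- NA_real_
  list(phase = out, valid = valid, support = den)
}

## ---- least-squares phase unwrapping --------------------------------------

#' Least-squares (Poisson) phase unwrapping
#'
#' Computes wrapped first differences of the phase in x and y, assigns
#' zero weight to differences crossing pixels outside `mask`, and finds
#' the unwrapped field minimizing the weighted squared deviation of its
#' gradients from the wrapped gradients. The normal equations are a
#' weighted discrete Poisson equation with Neumann boundary conditions
#' on the full rectangular grid; they are solved by conjugate gradients
#' preconditioned with the exact cosine-transform (DCT) solver of the
#' unweighted Poisson problem, so the uniform-weight case converges in
#' a single preconditioner application.
#'
#' The additive constant is fixed so that the certainty-weighted median
#' of (unwrapped - wrapped) over the mask equals the multiple of
#' \eqn{2\pi} nearest to it, i.e. the unwrapped field agrees with the
#' wrapped input modulo \eqn{2\pi} at the median pixel.
#'
#' For phase fields whose masked wrapped neighbour differences are all
#' consistent (residue-free inputs, e.g. any smooth field) the true
#' field is recovered on the mask exactly up to the additive constant.
#'
#' @param phase wrapped phase matrix.
#' @param mask logical matrix: pixels whose gradients participate.
#' @param certainty optional weights for the constant-fixing median
#'   (defaults to 1 on the mask).
#' @param tol relative residual tolerance of the conjugate-gradient
#'   solve.
#' @param max_iter iteration cap.
#' @return unwrapped phase matrix over the full grid; downstream
#'   consumers should read only masked pixels.
#' @export
unwrap_poisson <- function(phase, mask = NULL, certainty = NULL,
                           tol = 1e-12, max_iter = 500L) {
  nr <- nrow(phase); nc <- ncol(phase)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!any(mask)) abort("unwrap mask is empty", "degenerate_input_error")
  if (is.null(certainty)) certainty <- matrix(1, nr, nc)

  ph <- phase
  ph[is.na(ph)] <- 0
  # wrapped differences along rows (y, first index) and columns (x)
  dy <- wrap_phase(ph[-1, , drop = FALSE] - ph[-nr, , drop = FALSE])
  dx <- wrap_phase(ph[, -1, drop = FALSE] - ph[, -nc, drop = FALSE])
  wy <- (mask[-1, , drop = FALSE] & mask[-nr, , drop = FALSE]) * 1
  wx <- (mask[, -1, drop = FALSE] & mask[, -nc, drop = FALSE]) * 1

  div_w <- function(gx, gy) {
    out <- matrix(0, nr, nc)
    out[-nr, ] <- out[-nr, ] + gy
    out[-1, ]  <- out[-1, ]  - gy
    out[, -nc] <- out[, -nc] + gx
    out[, -1]  <- out[, -1]  - gx
    out
  }
  # normal equations D^T W D u = D^T W d, written with the positive
  # semidefinite operator A = -div(w grad .)
  apply_A <- function(u) {
    gy <- wy * (u[-1, , drop = FALSE] - u[-nr, , drop = FALSE])
    gx <- wx * (u[, -1, drop = FALSE] - u[, -nc, drop = FALSE])
    -div_w(gx, gy)
  }
  b <- -div_w(wx * dx, wy * dy)

  # preconditioner: exact inverse of the unweighted Neumann Laplacian
  # (positive-definite convention matching A)
  ey <- 2 - 2 * cos(pi * (0:(nr - 1)) / nr)
  ex <- 2 - 2 * cos(pi * (0:(nc - 1)) / nc)
  L <- outer(ey, ex, `+`)
  L[1, 1] <- 1
  precond <- function(r) {
    R <- dct2d(r) / L
    R[1, 1] <- 0
    idct2d(R)
  }

  u <- matrix(0, nr, nc)
  r <- b
  bnorm <- sqrt(sum(b * b))
  if (bnorm > 0) {
    z <- precond(r)
    p <- z
    rz <- sum(r * z)
    for (it in seq_len(max_iter)) {
      Ap <- apply_A(p)
      pAp <- sum(p * Ap)
      if (pAp <= 0) break
      alpha <- rz / pAp
      u <- u + alpha * p
      r <- r - alpha * Ap
      if (sqrt(sum(r * r)) <= tol * bnorm) break
      z <- precond(r)
      rz_new <- sum(r * z)
      beta <- rz_new / rz
      rz <- rz_new
      p <- z + beta * p
    }
  }

  d <- u - phase
  w <- certainty * mask
  m <- weighted_median(d[mask], w[mask])
  u - (m - 2 * pi * round(m / (2 * pi)))
}

## ---- displacement decoding -----------------------------------------------

#' Displacement field container
#'
#' Per-pixel 3-component displacement in mm with validity and certainty
#' maps. `u[, , 1:3]` are the x, y, z components; invalid pixels hold
#' `NA`, never a silent zero.
#'
#' @param u numeric array (nrow x ncol x 3), mm.
#' @param valid logical matrix.
#' @param certainty non-negative matrix (zero where invalid).
#' @param pixel_spacing (dx, dy) mm.
#' @export
displacement_field <- function(u, valid, certainty, pixel_spacing) {
  stopifnot(length(dim(u)) == 3, dim(u)[3] == 3)
  for (k in 1:3)
    if (any(!is.finite(u[, , k][valid])))
      stop("non-finite displacement on valid pixels")
  certainty[!valid] <- 0
  structure(list(u = u, valid = valid, certainty = certainty,
                 pixel_spacing = rep(pixel_spacing, length.out = 2)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  ip <- sqrt(x$u[, , 1]^2 + x$u[, , 2]^2)
  cat(sprintf(paste0("<displacement_field> %d x %d pixels, %d valid; ",
                     "median in-plane |u| %.3f mm\n"),
              dim(x$u)[1], dim(x$u)[2], sum(x$valid),
              stats::median(ip[x$valid])))
  invisible(x)
}

#' Decode 3-D displacement from processed net phases
#'
#' Solves, per pixel, the linear system
#' \eqn{2\pi k_e D u = \phi_{net}} in the least-squares sense, where the
#' rows of `D` are the net encoding directions (encoding direction minus
#' the reference acquisition's direction) and \eqn{\phi_{net}} the
#' corresponding reference-subtracted, smoothed and unwrapped phases.
#'
#' @param acq the originating [dense_acquisition()] (supplies `k_e` and
#'   encoding geometry).
#' @param net_phases list of unwrapped net-phase matrices, one per
#'   non-reference acquisition, in the order of `acq$phases` with the
#'   reference removed.
#' @param valid logical matrix of pixels where all net phases are valid.
#' @param certainty certainty propagated from the magnitude image.
#' @return a [displacement_field()].
#' @export
decode_displacement <- function(acq, net_phases, valid = NULL,
                                certainty = NULL) {
  D <- acq$encoding_directions
  Dn <- D[-acq$reference, , drop = FALSE] -
    matrix(D[acq$reference, ], nrow(D) - 1L, 3, byrow = TRUE)
  if (length(net_phases) != nrow(Dn))
    abort("one net phase image per non-reference acquisition required",
          "validation_error")
  if (qr(Dn)$rank < 3) {
    abort(paste0("net encoding directions span fewer than 3 dimensions; ",
                 "deficient direction space: rank ", qr(Dn)$rank),
          "encoding_configuration_error")
  }
  nr <- nrow(net_phases[[1]]); nc <- ncol(net_phases[[1]])
  if (is.null(valid)) {
    valid <- Reduce(`&`, lapply(net_phases, function(p) is.finite(p)))
  }
  if (is.null(certainty)) certainty <- acq$magnitude
  A <- 2 * pi * acq$k_e * Dn
  pinv <- solve(crossprod(A), t(A))          # 3 x m
  Phi <- do.call(rbind, lapply(net_phases, function(p) { p[!valid] <- 0; as.vector(p) }))
  U <- pinv %*% Phi                          # 3 x npix
  u <- array(NA_real_, c(nr, nc, 3))
  for (comp in 1:3) {
    m <- matrix(U[comp, ], nr, nc)
    m[!valid] <- NA_real_
    u[, , comp] <- m
  }
  displacement_field(u, valid, certainty, acq$pixel_spacing)
}

#' Full phase processing: smooth, unwrap, decode
#'
#' Applies the post-processing chain to an acquisition: per
#' non-reference acquisition, subtract the reference phase (mod
#' \eqn{2\pi}), smooth by certainty-weighted normalized averaging,
#' unwrap with the Poisson solver on the smoothing support region, then
#' decode 3-D displacement by least squares.
#'
#' The smoothing certainty is `magnitude^certainty_exponent`, zeroed
#' outside the wall mask; unwrapping operates on the Gaussian-dilated
#' support where the normalized convolution has valid output, so that
#' near-wall pixels carry smoothly extended phase for sub-pixel
#' interpolation.
#'
#' @param acq a [dense_acquisition()].
#' @param mask logical wall-pixel mask (from [build_wall_mask()]).
#' @param sigma_px Gaussian applicability standard deviation in pixels
#'   (default 1).
#' @param certainty_exponent exponent p in certainty = magnitude^p.
#' @return a [displacement_field()].
#' @export
process_acquisition <- function(acq, mask, sigma_px = 1,
                                certainty_exponent = 1) {
  cert <- acq$magnitude^certainty_exponent
  cert[!mask] <- 0
  idx <- setdiff(seq_along(acq$phases), acq$reference)
  ref <- acq$phases[[acq$reference]]
  nets <- vector("list", length(idx))
  valid <- NULL
  for (j in seq_along(idx)) {
    net <- wrap_phase(acq$phases[[idx[j]]] - ref)
    sm <- normalized_average(net, cert, sigma_px = sigma_px)
    un <- unwrap_poisson(sm$phase, mask = sm$valid, certainty = sm$support)
    un[!sm$valid] <- NA_real_
    nets[[j]] <- un
    valid <- if (is.null(valid)) sm$valid else valid & sm$valid
  }
  decode_displacement(acq, nets, valid = valid, certainty = acq$magnitude)
}
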