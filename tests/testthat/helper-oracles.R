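# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (direct summation, sequential unwrapping,
# polygonal arc length) so that agreement is evidence, not tautology.

# Brute-force Gaussian smoothing of the unit-complex phase representation:
# per-pixel windowed sum of g * exp(i phi) (zero padding), then arg.
brute_gauss_phase <- function(phase, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  nr <- nrow(phase); nc <- ncol(phase)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0 + 0i
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        g <- exp(-(di^2 + dj^2) / (2 * sigma^2))
        acc <- acc + g * exp(1i * phase[ii, jj])
      }
    }
    out[i, j] <- Arg(acc)
  }
  out
}

# Sequential (Itoh) 2-D unwrapping: integrate wrapped differences down the
# first column, then along each row.
itoh_unwrap <- function(phase) {
  nr <- nrow(phase); nc <- ncol(phase)
  out <- matrix(0, nr, nc)
  out[1, 1] <- phase[1, 1]
  for (i in 2:nr)
    out[i, 1] <- out[i - 1, 1] + wrap_phase(phase[i, 1] - phase[i - 1, 1])
  for (i in 1:nr) for (j in 2:nc)
    out[i, j] <- out[i, j - 1] + wrap_phase(phase[i, j] - phase[i, j - 1])
  out
}

# Random band-limited phase field with the requested total range, built
# from a handful of low-frequency cosine products.
random_smooth_field <- function(nr, nc, range) {
  f <- matrix(0, nr, nc)
  for (k in 1:5) {
    fy <- sample(0:3, 1); fx <- sample(0:3, 1)
    f <- f + stats::rnorm(1) *
      outer(cos(pi * fy * (0:(nr - 1)) / nr + stats::runif(1, 0, 2 * pi)),
            cos(pi * fx * (0:(nc - 1)) / nc + stats::runif(1, 0, 2 * pi)))
  }
  if (diff(range(f)) == 0) f[1, 1] <- f[1, 1] + 1
  f / diff(range(f)) * range
}

# Ground-truth circumferential stretch of a phantom by dense polygonal
# arc length: ratio of deformed to resting segment lengths of the
# mid-wall circle, sampled at the segment containing each theta.
polygonal_stretch_oracle <- function(spec, thetas, n = 1e5) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  rest <- cbind(spec$center[1] + spec$mid_radius * cos(th),
                spec$center[2] + spec$mid_radius * sin(th))
  def <- phantom_deform(spec, rest)
  len_rest <- sqrt(rowSums((rest[-1, ] - rest[-(n + 1), ])^2))
  len_def <- sqrt(rowSums((def[-1, ] - def[-(n + 1), ])^2))
  ratio <- len_def / len_rest
  idx <- pmin(n, pmax(1, floor((thetas %% (2 * pi)) / (2 * pi) * n) + 1))
  ratio[idx]
}

# quadrant angle convention: standard polar angle alpha of a point whose
# circumferential angle from the anterior axis is theta (default axes)
alpha_from_quadrant_theta <- function(theta) -theta - pi / 2

# closed-form two-way ANOVA sums of squares for a balanced design
anova_oracle <- function(tab) {
  y <- tab$stretch
  g <- tab$group; q <- tab$quadrant
  N <- length(y); gm <- mean(y)
  ss <- function(means, counts) sum(counts * (means - gm)^2)
  mg <- tapply(y, g, mean); ng <- table(g)
  mq <- tapply(y, q, mean); nq <- table(q)
  mgq <- tapply(y, list(g, q), mean); ngq <- table(g, q)
  ss_g <- ss(mg, ng)
  ss_q <- ss(mq, nq)
  ss_cells <- sum(ngq * (mgq - gm)^2)
  ss_int <- ss_cells - ss_g - ss_q
  ss_res <- sum((y - mgq[cbind(g, q)])^2)
  df_g <- nlevels(g) - 1; df_q <- nlevels(q) - 1
  df_int <- df_g * df_q; df_res <- N - nlevels(g) * nlevels(q)
  ms_res <- ss_res / df_res
  c(F_group = (ss_g / df_g) / ms_res,
    F_quadrant = (ss_q / df_q) / ms_res,
    F_interaction = (ss_int / df_int) / ms_res)
}

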