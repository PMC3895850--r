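circle_curve <- function(r, n = 32, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  fit_closed_curve(cbind(cx + r * cos(th), cy + r * sin(th)))
}

test_that("seeded points are equidistant and start on the anterior axis", {
  cv <- circle_curve(15)
  pts <- seed_points(cv, 100)
  ch <- sqrt(rowSums((pts[c(2:100, 1), ] - pts)^2))
  expect_lt(max(abs(ch / (2 * 15 * sin(pi / 100)) - 1)), 1e-3)
  # first point on the A axis (image -y from the centre)
  expect_equal(as.numeric(pts[1, ]), c(0, -15), tolerance = 1e-4)
  # ordering advances A -> R: second point has negative x
  expect_lt(pts[2, 1], 0)

  p8 <- seed_points(cv, 8)
  ang <- sort(atan2(p8[, 2], p8[, 1]) %% (2 * pi))
  expect_equal(diff(ang), rep(pi / 4, 7), tolerance = 1e-6)

  expect_error(seed_points(cv, 5), class = "parameter_error")
})

test_that("equal arc spacing holds on an ellipse against a polygonal oracle", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  cv <- fit_closed_curve(cbind(20 * cos(th), 9 * sin(th)))
  pts <- seed_points(cv, 64)
  # dense polygonal arc length between consecutive seeded points
  tt <- seq(0, 2 * pi, length.out = 1e5)
  poly <- cbind(20 * cos(tt), 9 * sin(tt))
  # the fitted spline differs from the exact ellipse by < 0.05%, so
  # compare spacing uniformity on the spline's own dense polygonization
  dense <- curve_points(cv, 1e5)
  seg <- sqrt(rowSums((dense[c(2:1e5, 1), ] - dense)^2))
  cum <- c(0, cumsum(seg))
  near <- function(p) which.min((dense[, 1] - p[1])^2 + (dense[, 2] - p[2])^2)
  s <- sort(cum[apply(pts, 1, near)])
  gaps <- diff(c(s, s[1] + cum[1e5 + 1]))
  expect_lt(max(abs(gaps / mean(gaps) - 1)), 1e-3)
})

test_that("tracking applies the displacement sign convention", {
  n <- 24
  mkfield <- function(ux, uy, uz) {
    u <- array(0, c(n, n, 3))
    u[, , 1] <- ux; u[, , 2] <- uy; u[, , 3] <- uz
    displacement_field(u, matrix(TRUE, n, n), matrix(1, n, n), 1)
  }
  pts <- cbind(10 + 3 * cos(seq(0, 2 * pi, length.out = 9)[-9]),
               10 + 3 * sin(seq(0, 2 * pi, length.out = 9)[-9]))
  tr0 <- track_points(pts, mkfield(0, 0, 0))
  expect_equal(tr0$systolic[, 1:2], tr0$diastolic[, 1:2], tolerance = 1e-12)
  expect_equal(tr0$systolic[, 3], rep(0, 8), ignore_attr = TRUE)

  tr1 <- track_points(pts, mkfield(-1, 0, 0))
  expect_equal(tr1$systolic[, 1] - tr1$diastolic[, 1], rep(1, 8),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("tracked points land on the true deformed mid-wall", {
  spec <- phantom_spec(s0 = 1.05, a = 0.02, phi = 1, rotation = 0.05,
                       through_plane_shift = 2)
  ph <- make_phantom(spec)
  field <- process_acquisition(ph$acquisition, ph$delineation$mask)
  pts <- seed_points(ph$delineation$mid, 100, center = ph$delineation$center)
  tr <- track_points(pts, field)
  truth <- ph$truth$deform(tr$diastolic[, 1:2])
  err <- sqrt(rowSums((tr$systolic - truth)^2))
  expect_lt(max(err), 0.05)
})

test_that("periodic spline fitting is exact on representable input", {
  set.seed(15)
  K <- 5
  coefs <- matrix(stats::rnorm(2 * K, sd = 3), K, 2) + c(10, 0)
  cv <- structure(list(coef = coefs, pieces = K, n_points = 40),
                  class = c("bspline_curve", "closed_curve"))
  pts <- curve_eval(cv, (0:39) / 40)
  fit <- fit_periodic_spline(pts, K)
  resid <- curve_eval(fit, (0:39) / 40) - pts
  expect_lt(max(abs(resid)), 1e-9)

  expect_error(fit_periodic_spline(pts[1:8, ], 5), class = "parameter_error")
})

test_that("5-piece spline fit of a circle preserves perimeter", {
  th <- 2 * pi * (0:99) / 100
  pts <- 15 * cbind(cos(th), sin(th))
  fit <- fit_periodic_spline(pts, 5)
  dense <- curve_eval(fit, seq(0, 1, length.out = 4001))
  r <- sqrt(rowSums(dense^2))
  # a 5-piece periodic cubic carries ~0.5% radial ripple on a circle,
  # but its perimeter matches to well below 0.05%
  expect_lt(max(abs(r - 15)) / 15, 6e-3)
  expect_lt(abs(curve_length(fit) / (2 * pi * 15) - 1), 5e-4)
})

test_that("spline regularization suppresses point jitter", {
  set.seed(16)
  th <- 2 * pi * (0:99) / 100
  clean <- 15 * cbind(cos(th), sin(th))
  noisy <- clean + matrix(stats::rnorm(200, sd = 0.3), ncol = 2)
  fit <- fit_periodic_spline(noisy, 5)
  proj <- project_onto_curve(fit, noisy)$points
  rms <- function(p) sqrt(mean((sqrt(rowSums(p^2)) - 15)^2))
  expect_lt(rms(proj), rms(noisy))
})

test_that("stretch profile is exact for identity, scaling and rigid motion", {
  th <- 2 * pi * (0:99) / 100
  dia <- cbind(40 + 15 * cos(th), 40 + 15 * sin(th), 0)
  mk <- function(sys) structure(list(diastolic = dia, systolic = sys, n = 100),
                                class = "tracked_points")
  ctr <- c(40, 40)

  lam_id <- stretch_profile(mk(dia), center = ctr)$lambda
  expect_equal(lam_id, rep(1, 100), tolerance = 1e-10)

  scl <- cbind(40 + 1.06 * 15 * cos(th), 40 + 1.06 * 15 * sin(th), 0)
  lam_s <- stretch_profile(mk(scl), center = ctr)$lambda
  expect_equal(lam_s, rep(1.06, 100), tolerance = 0.002)

  a <- 10 * pi / 180
  rot <- cbind(40 + 15 * cos(th + a), 40 + 15 * sin(th + a), 3)
  lam_r <- stretch_profile(mk(rot), center = ctr)$lambda
  expect_equal(lam_r, rep(1, 100), tolerance = 0.002)
})

test_that("through-plane motion enters systolic lengths in 3-D", {
  # tilt the systolic ring: z = h sin(theta) lengthens it measurably
  th <- 2 * pi * (0:99) / 100
  dia <- cbind(15 * cos(th), 15 * sin(th), 0)
  sys <- cbind(15 * cos(th), 15 * sin(th), 6 * sin(th))
  mk <- structure(list(diastolic = dia, systolic = sys, n = 100),
                  class = "tracked_points")
  lam <- stretch_profile(mk, center = c(0, 0))$lambda
  expect_gt(mean(lam), 1.01)
})

test_that("quadrant summary arithmetic and identities", {
  lam <- c(rep(1.08, 25), rep(1.04, 75))
  th <- (2 * pi * (0:99) / 100 + pi / 100)
  quad <- factor(rep(c("A", "R", "P", "L"), each = 25),
                 levels = c("A", "R", "P", "L"))
  prof <- structure(data.frame(segment = 1:100, lambda = lam, theta = th,
                               quadrant = quad),
                    class = c("stretch_profile", "data.frame"))
  qs <- quadrant_summary(prof)
  expect_equal(qs$s_overall, 1.05, tolerance = 1e-12)
  expect_equal(unname(qs$rel_diff["A"]), 0.03 / 1.05, tolerance = 1e-12)
  expect_equal(unname(qs$rel_diff["R"]), -0.01 / 1.05, tolerance = 1e-12)
  expect_equal(sum(qs$rel_diff), 0, tolerance = 1e-12)
  expect_equal(unname(qs$percent["overall"]), 105, tolerance = 1e-9)

  prof2 <- prof
  prof2$quadrant <- factor(rep("A", 100), levels = c("A", "R", "P", "L"))
  expect_error(quadrant_summary(prof2), "R", class = "analysis_error")
})
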