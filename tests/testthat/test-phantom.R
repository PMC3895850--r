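test_that("identity deformation yields identically zero phase images", {
  ph <- make_phantom(phantom_spec())
  for (p in ph$acquisition$phases)
    expect_equal(max(abs(p)), 0)
  expect_equal(max(abs(ph$truth$displacement)), 0)
})

test_that("encoding phase follows phi = 2 pi k_e (d . u), with wrapping", {
  # uniform through-plane shift gives a spatially constant encoded phase;
  # the tetrahedral net directions have z-component -1/sqrt(2)
  shift <- 3.125 * sqrt(2)              # d.u = 3.125 mm -> phase pi/2
  ph <- make_phantom(phantom_spec(through_plane_shift = shift))
  expect_equal(max(abs(ph$acquisition$phases[[2]] - pi / 2)), 0,
               tolerance = 1e-12)

  # displacement 6.5 mm along d: phase 1.04 pi stored as 1.04 pi - 2 pi
  shift2 <- 6.5 * sqrt(2)
  ph2 <- make_phantom(phantom_spec(through_plane_shift = shift2))
  expect_equal(ph2$acquisition$phases[[2]][1, 1], 1.04 * pi - 2 * pi,
               tolerance = 1e-9)
})

test_that("uniform radial expansion produces the expected in-plane displacement", {
  # s0 chosen so the mid-wall moves out by 3.125 mm everywhere
  spec <- phantom_spec(s0 = 1 + 3.125 / 15)
  ph <- make_phantom(spec)
  m <- ph$delineation$mask
  # at the pixel right of centre, u = (-3.125 - (r - R) correction, 0, 0)
  # for mid-wall pixels; test |u| at the exact mid-radius via the map
  p <- matrix(c(spec$center[1] + spec$mid_radius, spec$center[2]), 1)
  u <- p - phantom_deform(spec, p)[, 1:2]
  expect_equal(as.numeric(sqrt(sum(u^2))), 3.125, tolerance = 1e-12)
  # corresponding unwrapped in-plane phase magnitude is pi/2 per unit
  # in-plane encoding direction
  expect_equal(2 * pi * spec$k_e * 3.125, pi / 2, tolerance = 1e-12)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(wall_thickness = -1), class = "parameter_error")
  expect_error(phantom_spec(mid_radius = 1, wall_thickness = 3),
               class = "parameter_error")
  expect_error(phantom_spec(s0 = 0.5, a = 0.6, phi = 0),
               class = "parameter_error")
  expect_error(phantom_spec(lumen_magnitude = 2), class = "parameter_error")
  expect_error(phantom_spec(snr = -3, seed = 1), class = "parameter_error")
  expect_error(phantom_spec(snr = 20), class = "configuration_error")
})

test_that("same seed gives bit-identical phantoms", {
  a <- make_phantom(phantom_spec(snr = 10, seed = 99))
  b <- make_phantom(phantom_spec(snr = 10, seed = 99))
  expect_identical(a$acquisition$magnitude, b$acquisition$magnitude)
  expect_identical(a$acquisition$phases, b$acquisition$phases)
  c <- make_phantom(phantom_spec(snr = 10, seed = 100))
  expect_false(identical(a$acquisition$phases, c$acquisition$phases))
})

test_that("lumen magnitude sits below the downstream exclusion threshold", {
  ph <- make_phantom(phantom_spec())
  mag <- ph$acquisition$magnitude
  m <- ph$delineation$mask
  lum_r <- ph$spec$mid_radius - ph$spec$wall_thickness / 2 - 2 * ph$spec$pixel_spacing
  n <- ph$spec$grid_size; sp <- ph$spec$pixel_spacing
  xs <- (seq_len(n) - 1) * sp
  d <- sqrt(outer(xs - ph$spec$center[2], xs - ph$spec$center[1],
                  function(y, x) x^2 + y^2))
  lumen <- d < lum_r
  expect_true(all(mag[lumen] < 0.3 * stats::median(mag[m])))
})

test_that("analytic stretch profile matches closed forms and a polygonal oracle", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  # uniform scaling of a circle
  expect_equal(analytic_stretch_profile(phantom_spec(s0 = 1.17), th),
               rep(1.17, length(th)), tolerance = 1e-7)
  # rigid motion preserves arc length
  expect_equal(
    analytic_stretch_profile(
      phantom_spec(rotation = 0.4, through_plane_shift = 5), th),
    rep(1, length(th)), tolerance = 1e-7)
  # harmonic pattern vs brute-force polygonal arc length
  spec <- phantom_spec(s0 = 1.05, a = 0.03, phi = 0)
  got <- analytic_stretch_profile(spec, th)
  expect_equal(got, polygonal_stretch_oracle(spec, th), tolerance = 1e-6)
})

test_that("partial-volume area fractions are exact", {
  # disk fully containing / missing a pixel
  sq <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(circle_polygon_area(0, 0, 10, sq), 1.0)
  expect_equal(circle_polygon_area(20, 0, 10, sq), 0.0)
  # pixel straddling a gently curved circle edge; expected value frozen
  # from numerical integration of the covered width
  sq2 <- cbind(c(100, 101, 101, 100), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(circle_polygon_area(0, 0, 100.5, sq2), 0.4995854048,
               tolerance = 1e-9)
  # Monte-Carlo cross-check on a generic overlap
  set.seed(4)
  pts <- cbind(stats::runif(2e5, 1, 3), stats::runif(2e5, -1, 1))
  mc <- mean((pts[, 1]^2 + pts[, 2]^2) < 2.4^2) * 4
  rect <- cbind(c(1, 3, 3, 1), c(-1, -1, 1, 1))
  expect_equal(circle_polygon_area(0, 0, 2.4, rect), mc, tolerance = 0.02)
})

test_that("cine series endpoints, areas and scaling law behave", {
  spec <- phantom_spec()
  cs <- make_cine_series(spec, 12)
  expect_equal(relative_area_change(cs), 0, tolerance = 1e-12)

  spec2 <- phantom_spec(s0 = 1.2)
  cs2 <- make_cine_series(spec2, 2)
  # n_frames = 2: exactly the resting and deformed contours
  expect_equal(cs2$areas[2] / cs2$areas[1], 1.2^2, tolerance = 1e-12)
  cs20 <- make_cine_series(spec2, 20)
  expect_equal(relative_area_change(cs20), 1.2^2 - 1, tolerance = 1e-12)
  # max-area frame is the fully deformed state, min the resting state
  expect_equal(which.min(cs20$areas), 1L)

  expect_error(make_cine_series(spec, 1), class = "parameter_error")
})
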