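test_that("normalized averaging fixes constants and restores dropouts", {
  ph <- matrix(0.7, 16, 16)
  cert <- matrix(1, 16, 16)
  sm <- normalized_average(ph, cert)
  expect_equal(sm$phase, ph, tolerance = 1e-12)

  cert2 <- cert; cert2[8, 8] <- 0
  sm2 <- normalized_average(ph, cert2)
  expect_equal(sm2$phase[8, 8], 0.7, tolerance = 1e-12)

  expect_error(normalized_average(ph, cert * 0),
               class = "degenerate_input_error")
})

test_that("uniform certainty reduces to plain Gaussian smoothing of e^{i phi}", {
  set.seed(11)
  for (rep in 1:3) {
    f <- random_smooth_field(14, 17, 2.5)
    sm <- normalized_average(wrap_phase(f), matrix(1, 14, 17), sigma_px = 1)
    oracle <- brute_gauss_phase(wrap_phase(f), 1)
    expect_equal(sm$phase, oracle, tolerance = 1e-10)
  }
})

test_that("normalized averaging commutes with global phase rotation", {
  set.seed(12)
  f <- wrap_phase(random_smooth_field(16, 16, 3))
  cert <- matrix(stats::runif(256, 0.2, 1), 16, 16)
  a <- normalized_average(f, cert)$phase
  b <- normalized_average(wrap_phase(f + 1.234), cert)$phase
  expect_equal(wrap_phase(b - a - 1.234), matrix(0, 16, 16),
               tolerance = 1e-10)
})

test_that("poisson unwrapping recovers smooth and wrapped fields", {
  # no-wrap field: identity up to the constant-fixing rule
  set.seed(13)
  f <- random_smooth_field(32, 40, 5)
  un <- unwrap_poisson(wrap_phase(f))
  d <- un - f
  expect_lt(max(abs(d - mean(d))), 1e-6)

  # 6 pi linear ramp: agreement with sequential Itoh unwrapping
  ramp <- outer(rep(0, 32), seq(0, 6 * pi, length.out = 40), `+`) +
    outer(seq(0, 1.5, length.out = 32), rep(0, 40), `+`)
  unr <- unwrap_poisson(wrap_phase(ramp))
  oracle <- itoh_unwrap(wrap_phase(ramp))
  dd <- unr - oracle
  expect_lt(max(abs(dd - mean(dd))), 1e-6)

  # constant field passes through
  cst <- matrix(1.1, 20, 20)
  expect_equal(unwrap_poisson(cst), cst, tolerance = 1e-9)

  # output differs from input by near-exact multiples of 2 pi
  k <- (un - wrap_phase(f)) / (2 * pi)
  expect_lt(max(abs(k - round(k))), 1e-6)

  expect_error(unwrap_poisson(cst, mask = matrix(FALSE, 20, 20)),
               class = "degenerate_input_error")
})

test_that("unwrapping works on a masked annulus with wraps", {
  spec <- phantom_spec(through_plane_shift = 6.5 * sqrt(2))  # 1.04 pi phase
  ph <- make_phantom(spec)
  acq <- ph$acquisition
  cert <- acq$magnitude
  cert[!ph$delineation$mask] <- 0
  net <- wrap_phase(acq$phases[[2]] - acq$phases[[1]])
  sm <- normalized_average(net, cert)
  un <- unwrap_poisson(sm$phase, mask = sm$valid, certainty = sm$support)
  # true net phase is the constant 1.04 pi; the median rule keeps the
  # wrapped branch, i.e. 1.04 pi - 2 pi
  expect_equal(max(abs(un[ph$delineation$mask] - (1.04 * pi - 2 * pi))), 0,
               tolerance = 1e-6)
})

test_that("decoding inverts the encoding model", {
  n <- 6
  zero <- matrix(0, n, n)
  mk <- function(px, py, pz) {
    dense_acquisition(matrix(1, n, n),
                      list(zero, matrix(px, n, n), matrix(py, n, n),
                           matrix(pz, n, n)),
                      rbind(c(0, 0, 0), diag(3)), k_e = 0.08,
                      pixel_spacing = 2.3)
  }
  # zero phase -> zero displacement
  f0 <- decode_displacement(mk(0, 0, 0), list(zero, zero, zero))
  expect_equal(max(abs(f0$u)), 0)
  # net phase pi/2 on the x axis -> u_x = 3.125 mm
  f1 <- decode_displacement(mk(pi / 2, 0, 0),
                            list(matrix(pi / 2, n, n), zero, zero))
  expect_equal(f1$u[3, 3, 1], 3.125, tolerance = 1e-12)
  expect_equal(f1$u[3, 3, 2], 0, tolerance = 1e-12)

  # linearity
  set.seed(14)
  p1 <- lapply(1:3, function(i) matrix(stats::rnorm(n * n, sd = 0.3), n, n))
  p2 <- lapply(1:3, function(i) matrix(stats::rnorm(n * n, sd = 0.3), n, n))
  acq <- mk(0, 0, 0)
  fa <- decode_displacement(acq, p1)$u
  fb <- decode_displacement(acq, p2)$u
  fab <- decode_displacement(acq, Map(`+`, p1, p2))$u
  expect_equal(fab, fa + fb, tolerance = 1e-10)

  # deficient direction set is named
  bad <- dense_acquisition(matrix(1, n, n), list(zero, zero, zero),
                           rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                           k_e = 0.08, pixel_spacing = 2.3)
  expect_error(decode_displacement(bad, list(zero, zero)),
               "rank", class = "encoding_configuration_error")
})

test_that("noise-free phantom phases decode to the exact displacement", {
  ph <- make_phantom(phantom_spec(s0 = 1.06, rotation = 0.1,
                                  through_plane_shift = 2))
  acq <- ph$acquisition
  nets <- lapply(2:4, function(a)
    wrap_phase(acq$phases[[a]] - acq$phases[[acq$reference]]))
  f <- decode_displacement(acq, nets)
  for (k in 1:3) {
    err <- f$u[, , k] - ph$truth$displacement[, , k]
    expect_lt(max(abs(err[ph$delineation$mask])), 1e-6)
  }
})

test_that("processed displacement stays accurate under noise", {
  spec <- phantom_spec(snr = 20, seed = 7)
  ph <- make_phantom(spec)
  f <- process_acquisition(ph$acquisition, ph$delineation$mask)
  m <- ph$delineation$mask & f$valid
  err2 <- Reduce(`+`, lapply(1:3, function(k)
    (f$u[, , k] - ph$truth$displacement[, , k])^2))
  expect_lt(sqrt(mean(err2[m])), 0.1 * spec$pixel_spacing)
})
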