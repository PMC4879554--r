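test_that("SG first derivative is exact on linear ramps and constants", {
  wn <- seq(700, 899)
  ramp <- raman_spectrum(wn, 2 * wn + 5)
  d <- sg_first_derivative(ramp, 3, 1)
  expect_equal(d$intensities, rep(2, 200), tolerance = 1e-10)
  flat <- raman_spectrum(wn, rep(7, 200))
  expect_equal(sg_first_derivative(flat, 3, 1)$intensities, rep(0, 200),
               tolerance = 1e-12)
})

test_that("SG derivative matches the analytic cosine on a fine grid", {
  wn <- seq(700, 720, by = 0.01)
  s <- raman_spectrum(wn, sin(wn))
  d <- sg_first_derivative(s, 5, 2)
  interior <- 3:(length(wn) - 2)
  expect_lt(max(abs(d$intensities[interior] - cos(wn[interior]))), 1e-3)
})

test_that("derivative is affine-invariant in the offset and linear in scale", {
  set.seed(1)
  s <- toy_spectrum(50, intensities = rnorm(50))
  a <- 3.2; b <- -11
  s2 <- s; s2$intensities <- a * s$intensities + b
  expect_equal(sg_first_derivative(s2)$intensities,
               a * sg_first_derivative(s)$intensities, tolerance = 1e-10)
})

test_that("SG derivative preconditions are enforced", {
  s <- raman_spectrum(c(700:706, 710), 1:8)
  expect_error(sg_first_derivative(s), "interpolate")
  expect_error(sg_first_derivative(toy_spectrum(8), window = 9), "smaller")
  expect_error(sg_first_derivative(toy_spectrum(8), window = 4), "odd")
})

test_that("SG smoothing preserves lines, damps noise and spreads impulses", {
  wn <- seq(700, 799)
  ramp <- raman_spectrum(wn, 0.5 * wn - 3)
  expect_equal(sg_smooth(ramp, 3)$intensities, ramp$intensities,
               tolerance = 1e-9)
  set.seed(5)
  vr <- replicate(20, {
    s <- raman_spectrum(wn, rnorm(100))
    var(sg_smooth(s, 5)$intensities) / var(s$intensities)
  })
  expect_lt(median(vr), 1)
  imp <- raman_spectrum(wn, c(rep(0, 50), 1, rep(0, 49)))
  sm <- sg_smooth(imp, 3, 1)$intensities
  # window-3 order-1 SG weights are the 1/3 moving average
  expect_equal(sm[50:52], rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(sum(sm[49:53]), 1, tolerance = 1e-10)
})

test_that("region interpolation hits the exact grid and is idempotent", {
  wn <- seq(650, 1850, by = 0.7)
  s <- raman_spectrum(wn, rnorm(length(wn)))
  g <- interpolate_region(s, "fingerprint", 1)
  expect_equal(g$wavenumbers, seq(700, 1800))
  expect_length(g$wavenumbers, 1101)
  expect_equal(interpolate_region(g, "fingerprint", 1)$intensities,
               g$intensities)
  expect_error(interpolate_region(toy_spectrum(16), "fingerprint"),
               "outside spectrum support")
})

test_that("linear interpolation reproduces piecewise-linear inputs exactly", {
  knots <- c(700, 780, 840, 1000, 1100, 1300, 1500, 1650, 1800)
  vals <- c(0, 2, 4, -1, -2, 3, 6, 2, 1)
  s <- raman_spectrum(knots, vals)
  g <- interpolate_region(s, "fingerprint", 1)
  truth <- approx(knots, vals, xout = g$wavenumbers)$y
  expect_equal(g$intensities, truth)
})

test_that("vector normalization yields unit norm and fixed points", {
  s <- raman_spectrum(700:707, c(3, 4, rep(0, 6)))
  v <- vector_normalize(s)
  expect_equal(v$intensities[1:2], c(0.6, 0.8))
  expect_equal(sqrt(sum(v$intensities^2)), 1, tolerance = 1e-12)
  expect_equal(vector_normalize(v)$intensities, v$intensities,
               tolerance = 1e-12)
  set.seed(2)
  r <- vector_normalize(toy_spectrum(64, intensities = rnorm(64, sd = 40)))
  expect_equal(sqrt(sum(r$intensities^2)), 1, tolerance = 1e-12)
  z <- toy_spectrum(8, intensities = rep(0, 8))
  expect_error(vector_normalize(z), "all-zero")
})

test_that("baseline correction annihilates polynomials of its order", {
  wn <- seq(700, 1800)
  u <- (wn - 1250) / 550
  poly5 <- 3 - 2 * u + u^2 - 0.5 * u^3 + 0.2 * u^4 - 0.1 * u^5
  s <- raman_spectrum(wn, poly5)
  out <- baseline_correct(s, 5)
  expect_lt(max(abs(out$intensities)), 1e-8 * max(abs(poly5)))
  flat <- raman_spectrum(wn, rep(4, length(wn)))
  expect_lt(max(abs(baseline_correct(flat, 5)$intensities)), 1e-10)
})

test_that("baseline correction recovers a peak on a polynomial background", {
  wn <- seq(700, 1800)
  u <- (wn - 1250) / 550
  base <- 5 + 2 * u - u^2 + 0.3 * u^3
  peak <- 2 * lorentz(wn, 1447, 8)
  out <- baseline_correct(raman_spectrum(wn, base + peak), 5)
  off <- abs(wn - 1447) > 80
  # off-peak residual small relative to the peak height
  expect_lt(max(abs(out$intensities[off])), 0.15)
  expect_gt(out$intensities[wn == 1447], 1.5)
  # idempotence: residual already orthogonal to the polynomial basis
  again <- baseline_correct(out, 5)
  expect_equal(again$intensities, out$intensities, tolerance = 1e-8)
})

test_that("background subtraction identities hold", {
  set.seed(3)
  s <- toy_spectrum(40, intensities = rnorm(40) + 10)
  expect_equal(subtract_background(s, s)$intensities, rep(0, 40))
  zero <- toy_spectrum(40, intensities = rep(0, 40))
  expect_equal(subtract_background(s, zero)$intensities, s$intensities)
  wn <- seq(690, 1810)
  base <- 0.002 * (wn - 700) + 3
  sig <- raman_spectrum(wn, 5 * lorentz(wn, 1305, 8) + base)
  bg <- raman_spectrum(wn, base)
  clean <- subtract_background(sig, bg)
  off <- abs(wn - 1305) > 200
  expect_lt(max(abs(clean$intensities[off] - 5 * lorentz(wn[off], 1305, 8))),
            1e-9)
  short_bg <- raman_spectrum(seq(800, 900), rep(1, 101))
  expect_error(subtract_background(sig, short_bg), "covers")
})

test_that("classification pipeline is deterministic, unit-norm, right shape", {
  cfg <- sim_config(n_per_group = 4, seed = 9)
  set <- simulate_set(list(P = profile_preset("parent"),
                           R = profile_preset("recurrent")), cfg)
  p1 <- classification_pipeline(set)
  p2 <- classification_pipeline(set)
  expect_identical(set_matrix(p1), set_matrix(p2))
  m <- set_matrix(p1)
  expect_equal(dim(m), c(8, 1101))
  expect_equal(sqrt(rowSums(m^2)), rep(1, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(p1$common_axis, seq(700, 1800))
  # identical raw input spectra give identical processed vectors
  twin <- raman_set(list(set$spectra[[1]], set$spectra[[1]]))
  tm <- set_matrix(classification_pipeline(twin))
  expect_identical(tm[1, ], tm[2, ])
})
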