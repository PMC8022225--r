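test_that("per-frame normalization removes photobleaching", {
  nx <- 40; nt <- 30
  base <- rep(1, nx)
  bleach <- exp(-(0:(nt - 1)) / 10)
  profiles <- outer(bleach, base)
  k <- build_kymograph(profiles, times = 2 * (0:(nt - 1)), length_um = 4)
  # identical columns after normalization despite the decay
  expect_lt(max(apply(k$intensity, 2, function(col) diff(range(col)))),
            1e-12)
  # normalization makes the result invariant to any global intensity factor
  k2 <- build_kymograph(profiles * rep(stats::runif(nt, 0.5, 5), nx),
                        times = 2 * (0:(nt - 1)), length_um = 4)
  expect_equal(k2$intensity, k$intensity, tolerance = 1e-12)
})

test_that("too few frames or ragged profiles are rejected", {
  expect_error(build_kymograph(matrix(1, 1, 10), times = 0,
                               length_um = 3), "at least 4")
  expect_error(build_kymograph(list(rep(1, 5), rep(1, 6), rep(1, 5),
                                    rep(1, 5)),
                               times = 0:3, length_um = 3), "ragged")
})

test_that("the time-averaged profile is the frame mean", {
  set.seed(24)
  profiles <- matrix(stats::runif(200), nrow = 10)
  k <- build_kymograph(profiles, times = 0:9, length_um = 5,
                       normalize = FALSE)
  expect_equal(time_average_profile(k), colMeans(profiles))
})

test_that("half-cell signals split symmetrically and conserve intensity", {
  nx <- 41  # odd: middle sample shared between halves
  x <- seq(0, 1, length.out = nx)
  sym <- outer(rep(1, 8), exp(-(x - 0.5)^2 / 0.02))
  k <- build_kymograph(sym, times = 0:7, length_um = 4,
                       normalize = FALSE)
  hs <- half_cell_signals(k)
  expect_equal(hs$F_left, hs$F_right, tolerance = 1e-9)
  expect_equal(hs$F_left + hs$F_right, rowSums(k$intensity),
               tolerance = 1e-12)
})

test_that("an antisymmetric standing wave anticorrelates the halves", {
  nx <- 60; nt <- 60
  x <- seq(0, 1, length.out = nx)
  t <- seq(0, 118, length.out = nt)
  f <- 1 + 0.8 * cos(2 * pi * t / 17) %o% sin(2 * pi * x)
  k <- build_kymograph(pmax(f, 0), times = t, length_um = 10,
                       normalize = FALSE)
  hs <- half_cell_signals(k)
  expect_lt(stats::cor(hs$F_left, hs$F_right), -0.95)
})

test_that("the trigonometric fit recovers a 17 s period", {
  t <- seq(0, 118, by = 2)
  trace <- 5 + 2 * cos(2 * pi * t / 17)
  fit <- fit_period(trace, t)
  expect_lt(abs(fit$period - 17), 0.2)
  expect_equal(fit$period, 2 * pi / fit$omega, tolerance = 1e-12)
  # phase-shifted input: same period, rotated (a, b), same amplitude
  trace2 <- 5 + 2 * cos(2 * pi * t / 17 - 1.1)
  fit2 <- fit_period(trace2, t)
  expect_lt(abs(fit2$period - 17), 0.2)
  expect_equal(fit2$amplitude, fit$amplitude, tolerance = 0.05)
  expect_equal(sqrt(fit2$a^2 + fit2$b^2), sqrt(fit$a^2 + fit$b^2),
               tolerance = 0.05)
})

test_that("a constant trace raises the no-oscillation condition", {
  t <- seq(0, 118, by = 2)
  expect_error(fit_period(rep(3, length(t)), t),
               class = "tracksearch_no_oscillation")
  set.seed(25)
  expect_error(fit_period(3 + stats::rnorm(length(t), sd = 0.3), t),
               class = "tracksearch_no_oscillation")
})

test_that("wavelength equals the minima spacing of the averaged profile", {
  # F(x) = cos^2(2 pi x / 10) over 30 um: minima every 5 um (hand check)
  nx <- 301
  x <- seq(0, 30, length.out = nx)
  prof <- outer(rep(1, 6), cos(2 * pi * x / 10)^2)
  k <- build_kymograph(prof + 1e-6, times = 0:5, length_um = 30,
                       normalize = FALSE)
  lam <- wavelength_from_profile(k)
  expect_lt(abs(lam - 5) / 5, 0.03)
  # uniform intensity scaling leaves the spacing unchanged
  k2 <- build_kymograph(prof * 40 + 1e-6, times = 0:5, length_um = 30,
                        normalize = FALSE)
  expect_equal(wavelength_from_profile(k2), lam, tolerance = 1e-9)
  # peak mode measures the same spacing for this profile
  expect_lt(abs(wavelength_from_profile(k, filamentous = FALSE) - 5) / 5,
            0.03)
})

test_that("a monotone profile has no measurable wavelength", {
  prof <- outer(rep(1, 5), seq(1, 2, length.out = 50))
  k <- build_kymograph(prof, times = 0:4, length_um = 10,
                       normalize = FALSE)
  expect_error(wavelength_from_profile(k), "extrema")
})

test_that("noisy standing waves are recovered within 5%", {
  # standing wave over 2.5 spatial periods: nodes every 5 um, period 17 s
  nx <- 300; L <- 25
  x <- seq(0, L, length.out = nx)
  t <- seq(0, 136, by = 2)
  lam_star <- 10
  f <- (1 + cos(2 * pi * t / 17) %o% cos(2 * pi * x / lam_star))^2
  set.seed(26)
  noise <- matrix(stats::rnorm(length(t) * nx, sd = 0.2), length(t), nx)
  k <- build_kymograph(pmax(f + noise, 1e-6), times = t, length_um = L)
  hs <- half_cell_signals(k)
  osc <- fit_period(hs$F_left - hs$F_right, t)
  expect_lt(abs(osc$period - 17) / 17, 0.05)
  lam <- wavelength_from_profile(k)
  expect_lt(abs(lam - lam_star / 2) / (lam_star / 2), 0.05)
})
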