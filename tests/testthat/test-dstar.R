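test_that("track D* reproduces the one-step MSD formula", {
  dt <- 0.015
  # stationary track
  still <- data.frame(frame = 0:4, x_um = 1, y_um = 2)
  expect_equal(track_dstar(still, dt), 0)
  # hand arithmetic: equal 0.1 um steps in x
  tr <- data.frame(frame = 0:4, x_um = seq(0, 0.4, by = 0.1), y_um = 0)
  expect_equal(track_dstar(tr, dt), 0.04 / (4 * 4 * dt))
  expect_equal(track_dstar(tr, dt), 1 / 6)
})

test_that("long tracks are truncated after the 5th localization", {
  dt <- 0.015
  tr <- data.frame(frame = 0:9,
                   x_um = c(rep(0, 5), cumsum(rep(5, 5))), y_um = 0)
  expect_equal(track_dstar(tr, dt), 0)
})

test_that("short or gap-broken tracks are rejected and counted", {
  dt <- 0.015
  expect_true(is.na(track_dstar(data.frame(frame = 0:3, x_um = 0,
                                           y_um = 0), dt)))
  gap <- data.frame(frame = c(0, 1, 2, 4, 5), x_um = 0, y_um = 0)
  expect_true(is.na(track_dstar(gap, dt)))
  tracks <- rbind(
    data.frame(track_id = 1, frame = 0:4, x_um = 0, y_um = 0,
               cell_id = 1),
    data.frame(track_id = 2, frame = c(0, 1, 2, 4, 5), x_um = 1,
               y_um = 1, cell_id = 1),
    data.frame(track_id = 3, frame = 0:2, x_um = 2, y_um = 2,
               cell_id = 2))
  s <- dstar_sample(tracks, dt)
  expect_equal(nrow(s), 1L)
  expect_equal(attr(s, "n_rejected"), 2L)
})

test_that("the D* sampling density is the stated gamma law", {
  # printed-formula value at n = 4, D = 1, x = 1: 256 e^-4 / 6
  expect_equal(dstar_pdf(1, D = 1, n = 4), 256 * exp(-4) / 6,
               tolerance = 1e-12)
  # proper density for several (D, n)
  for (D in c(0.1, 1, 5)) {
    for (n in c(1, 4, 8)) {
      I <- stats::integrate(dstar_pdf, 0, Inf, D = D, n = n)$value
      expect_equal(I, 1, tolerance = 1e-6)
      m1 <- stats::integrate(function(x) x * dstar_pdf(x, D, n), 0,
                             Inf)$value
      m2 <- stats::integrate(function(x) x^2 * dstar_pdf(x, D, n), 0,
                             Inf)$value
      expect_equal(m1, D, tolerance = 1e-6)
      expect_equal(m2 - m1^2, D^2 / n, tolerance = 1e-5)
    }
  }
  expect_error(dstar_pdf(1, D = 0), "positive")
})

test_that("single-species MLE is the sample mean and is unbiased", {
  set.seed(8)
  v <- stats::rgamma(10000, shape = 4, rate = 4 / 0.5)
  f <- fit_single(as_sample <- tracksearch:::as_dstar_sample(v))
  expect_equal(f$D, mean(v))
  expect_lt(abs(f$D - 0.5), 3 * 0.5 / (2 * 100))
  expect_true(f$ci[1] < f$D && f$D < f$ci[2])
  # single value: estimate equals the value
  expect_equal(fit_single(tracksearch:::as_dstar_sample(0.7))$D, 0.7)
  # bias over replicates is negligible
  set.seed(9)
  reps <- replicate(300, mean(stats::rgamma(200, shape = 4, rate = 4)))
  expect_lt(abs(mean(reps) - 1), 3 * sd(reps) / sqrt(300))
  expect_error(fit_single(tracksearch:::as_dstar_sample(rep(0, 5))),
               "degenerate")
})

test_that("two-species mixture fit recovers known parameters", {
  set.seed(10)
  n <- 20000
  z <- stats::runif(n) < 0.3
  v <- ifelse(z, stats::rgamma(n, 4, rate = 4 / 0.1),
              stats::rgamma(n, 4, rate = 4 / 1.0))
  fit <- fit_mixture(v)
  expect_lt(abs(fit$A - 0.3), 0.02)
  expect_lt(abs(fit$D1 - 0.1) / 0.1, 0.10)
  expect_lt(abs(fit$D2 - 1.0) / 1.0, 0.10)
  expect_true(fit$D1 <= fit$D2)
})

test_that("a pure single species yields no significant immobile fraction", {
  set.seed(11)
  v <- stats::rgamma(5000, 4, rate = 4 / 0.8)
  fit <- fit_mixture(v)
  # any fitted minor component is not significantly above zero
  if (fit$A < 0.5) {
    expect_lte(fit$ci[1, "A"], 1e-6)
  } else {
    expect_gte(fit$ci[2, "A"], 1 - 1e-6)
  }
  # two-species likelihood can never fall below the nested single fit
  single <- fit_single(tracksearch:::as_dstar_sample(v))
  expect_gte(fit$loglik, single$loglik - 1e-6)
})

test_that("cell bootstrap gives percentile intervals around the estimate", {
  set.seed(12)
  per_cell <- stats::rgamma(40, 4, rate = 4)
  v <- rep(per_cell, times = 8)
  cells <- rep(seq_len(40), times = 8)
  s <- tracksearch:::as_dstar_sample(v, cell_id = cells)
  bs <- bootstrap_cells(s, "single", n_boot = 200, seed = 1)
  expect_true(bs$ci[1, "D"] <= bs$estimate[["D"]] &&
                bs$estimate[["D"]] <= bs$ci[2, "D"])
  # identical cells: no between-cell variance, interval collapses
  v2 <- rep(per_cell[1], 200)
  s2 <- tracksearch:::as_dstar_sample(v2, cell_id = rep(1:10, each = 20))
  bs2 <- bootstrap_cells(s2, "single", n_boot = 100, seed = 1)
  expect_lt(diff(bs2$ci[, "D"]), 1e-9)
  # a single cell cannot be resampled
  s3 <- tracksearch:::as_dstar_sample(v2, cell_id = 1L)
  expect_error(bootstrap_cells(s3, "single"), "two distinct cells")
})

test_that("classification threshold separates the populations as stated", {
  expect_equal(as.character(classify_tracks(0)), "immobile")
  expect_equal(as.character(classify_tracks(0.15)), "mobile")
  expect_equal(as.character(classify_tracks(0.1499)), "immobile")
  # label error rate matches the analytic overlap of the two gamma laws
  set.seed(13)
  n <- 20000
  z <- stats::runif(n) < 0.5
  v <- ifelse(z, stats::rgamma(n, 4, rate = 4 / 0.04),
              stats::rgamma(n, 4, rate = 4 / 1.0))
  lab <- classify_tracks(v)
  err <- mean((z & lab == "mobile") | (!z & lab == "immobile"))
  err_analytic <- 0.5 * stats::pgamma(0.15, 4, rate = 4 / 0.04,
                                      lower.tail = FALSE) +
    0.5 * stats::pgamma(0.15, 4, rate = 4 / 1.0)
  expect_lt(abs(err - err_analytic), 0.01)
})

test_that("localization-error corrections subtract the stated offsets", {
  dt <- 0.01548
  expect_equal(offset_correct(0.035^2 / dt, 0.035, dt), 0)
  expect_equal(offset_correct(0.11, 0.035, dt), 0.11 - 0.035^2 / dt)
  expect_lt(abs(offset_correct(0.11, 0.035, dt) - 0.031), 5e-4)
  expect_equal(offset_correct(0.01, 0.035, dt), 0)  # floored at zero
  expect_equal(baseline_correct(0.11, 0.07), 0.04)
})
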