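test_that("an emitter-free movie is pure Poisson background", {
  empty <- data.frame(frame = integer(), x_um = numeric(),
                      y_um = numeric())
  stack <- render_movie(empty, psf_sigma = 0.12, photons_per_frame = 500,
                        background = 3, dim = c(16L, 16L), n_frames = 200L,
                        seed = 2)
  px <- unlist(stack$frames)
  expect_lt(abs(mean(px) - 3), 0.05)
  expect_lt(abs(var(px) - 3) / 3, 0.1)   # Poisson: variance equals mean
  expect_true(all(px >= 0) && all(px == round(px)))
  # and detection finds nothing above any reasonable threshold
  cand <- detect_candidates(stack, threshold = 5)
  expect_equal(nrow(cand), 0L)
})

test_that("a noiseless emitter conserves its photon budget", {
  loc <- data.frame(frame = 0L, x_um = 16 * 0.096 / 2,
                    y_um = 16 * 0.096 / 2)
  stack <- render_movie(loc, psf_sigma = 0.1, photons_per_frame = 1000,
                        background = 0, dim = c(16L, 16L), noise = FALSE)
  expect_equal(sum(stack$frames[[1]]), 1000, tolerance = 1e-3)
})

test_that("shot noise is Poisson pixel-wise", {
  loc <- data.frame(frame = 0:499, x_um = 0.8, y_um = 0.8)
  stack <- render_movie(loc, psf_sigma = 0.1, photons_per_frame = 300,
                        background = 2, dim = c(16L, 16L), seed = 3)
  cube <- simplify2array(stack$frames)
  m <- apply(cube, c(1, 2), mean)
  v <- apply(cube, c(1, 2), var)
  bright <- m > 5
  expect_gt(sum(bright), 3)
  expect_lt(max(abs(v[bright] / m[bright] - 1)), 0.35)
})

test_that("two separated emitters give exactly two candidates per frame", {
  px <- 0.096
  locs <- rbind(data.frame(frame = 0:9, x_um = 6 * px, y_um = 6 * px),
                data.frame(frame = 0:9, x_um = 26 * px, y_um = 26 * px))
  stack <- render_movie(locs, psf_sigma = 0.12,
                        photons_per_frame = 5000, background = 1,
                        dim = c(32L, 32L), seed = 4)
  cand <- detect_candidates(stack, threshold = 8)
  expect_equal(as.vector(table(cand$frame)), rep(2L, 10))
  # detections never exceed the true emitter count at high SNR
  expect_lte(nrow(cand), 20L)
})

test_that("detection rate is non-decreasing with SNR", {
  px <- 0.096
  loc <- data.frame(frame = 0:29, x_um = 10 * px, y_um = 10 * px)
  rate <- vapply(c(30, 100, 400, 2000), function(photons) {
    stack <- render_movie(loc, psf_sigma = 0.12,
                          photons_per_frame = photons, background = 2,
                          dim = c(20L, 20L), seed = 5)
    nrow(detect_candidates(stack, threshold = 4)) / 30
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_equal(rate[4], 1)
})

test_that("elliptical Gaussian fitting reaches sub-tenth-pixel precision", {
  px <- 0.096
  truth <- c(5.30, 7.80)  # pixel coordinates
  loc <- data.frame(frame = 0:19, x_um = truth[1] * px,
                    y_um = truth[2] * px)
  stack <- render_movie(loc, psf_sigma = 0.12,
                        photons_per_frame = 10000, background = 2,
                        dim = c(16L, 16L), seed = 6)
  cand <- detect_candidates(stack, threshold = 10)
  fit <- localize(stack, cand, window = 9L)
  expect_gte(nrow(fit), 18L)
  err_px <- sqrt((fit$x_um / px - truth[1])^2 +
                   (fit$y_um / px - truth[2])^2)
  expect_lt(sqrt(mean(err_px^2)), 0.1)
  # isotropic PSF: widths agree and the angle is flagged unidentifiable
  expect_lt(median(abs(fit$width_x_um - fit$width_y_um)) /
              median(fit$width_x_um), 0.2)
  expect_gt(mean(!fit$angle_identifiable), 0.5)
})

test_that("localization error scales like the Thompson shot-noise limit", {
  px <- 0.096
  psf <- 0.12
  loc <- data.frame(frame = 0:39, x_um = 8.3 * px, y_um = 8.6 * px)
  stack <- render_movie(loc, psf_sigma = psf, photons_per_frame = 1000,
                        background = 0, dim = c(16L, 16L), seed = 7)
  cand <- detect_candidates(stack, threshold = 4)
  fit <- localize(stack, cand, window = 11L)
  err <- sqrt((fit$x_um - 8.3 * px)^2 + (fit$y_um - 8.6 * px)^2)
  rms <- sqrt(mean(err^2))
  limit <- psf / sqrt(1000) * sqrt(2)   # two coordinates
  expect_lt(rms, 1.5 * limit)
  expect_gt(rms, limit / 3)
})

test_that("simulate-render-localize round trip recovers the emitters", {
  px <- 0.096
  grid <- expand.grid(x = c(5, 15, 25), y = c(5, 15, 25))
  locs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(frame = 0:4, x_um = grid$x[i] * px, y_um = grid$y[i] * px)
  }))
  stack <- render_movie(locs, psf_sigma = 0.12,
                        photons_per_frame = 8000, background = 2,
                        dim = c(32L, 32L), seed = 8)
  cand <- detect_candidates(stack, threshold = 10)
  fit <- localize(stack, cand, window = 9L)
  recovered <- 0L
  for (i in seq_len(nrow(grid))) {
    for (f in 0:4) {
      hit <- fit$frame == f &
        abs(fit$x_um - grid$x[i] * px) < 0.5 * px &
        abs(fit$y_um - grid$y[i] * px) < 0.5 * px
      if (any(hit)) recovered <- recovered + 1L
    }
  }
  expect_gte(recovered / (nrow(grid) * 5), 0.99)
})

test_that("frame stacks round-trip through multi-page TIFF", {
  loc <- data.frame(frame = 0:3, x_um = 0.7, y_um = 0.9)
  stack <- render_movie(loc, psf_sigma = 0.1, photons_per_frame = 500,
                        background = 1, dim = c(12L, 12L), seed = 9)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(stack, path)
  back <- read_movie(path)
  expect_equal(length(back$frames), 4L)
  expect_equal(back$pixel_size, stack$pixel_size)
  expect_equal(back$frames[[2]], stack$frames[[2]], tolerance = 1e-5)
})

test_that("emitters outside the raster are clipped with a warning", {
  loc <- data.frame(frame = 0L, x_um = 100, y_um = 100)
  expect_warning(render_movie(loc, psf_sigma = 0.1,
                              photons_per_frame = 100, dim = c(8L, 8L),
                              noise = FALSE), "clipped")
})
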