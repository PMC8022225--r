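#' Render a synthetic fluorescence movie
#'
#' Renders ground-truth emitter positions into a camera image stack: each
#' emitter is drawn as a 2D Gaussian point-spread function integrated over
#' the pixel grid, a uniform background is added, and Poisson shot noise is
#' applied per pixel. Pixel `(i, j)` (0-based) covers
#' `[j, j+1) x [i, i+1)` pixels, so a position in µm maps to pixel
#' coordinates by dividing by `pixel_size` (pixel centers at half-integer
#' coordinates).
#'
#' @param locs Data frame with columns `frame` (0-based), `x_um`, `y_um`.
#' @param psf_sigma PSF standard deviation (µm).
#' @param photons_per_frame Expected photons per emitter per frame.
#' @param background Expected background photons per pixel per frame.
#' @param pixel_size Pixel size (µm, default 0.096).
#' @param dim Image size `c(rows, cols)` in pixels.
#' @param n_frames Number of frames; defaults to `max(frame) + 1`.
#' @param noise Apply Poisson noise (default `TRUE`).
#' @param seed Integer seed (used when `noise`).
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   matrices) and `pixel_size`.
#' @export
render_movie <- function(locs, psf_sigma, photons_per_frame,
                         background = 0, pixel_size = 0.096,
                         dim = c(32L, 32L), n_frames = NULL,
                         noise = TRUE, seed = 1L) {
  stopifnot(psf_sigma > 0, photons_per_frame >= 0, background >= 0,
            pixel_size > 0)
  if (is.null(n_frames)) {
    n_frames <- if (nrow(locs)) max(locs$frame) + 1L else 1L
  }
  nr <- dim[1L]; nc <- dim[2L]
  s_px <- psf_sigma / pixel_size
  if (noise) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  frames <- vector("list", n_frames)
  clipped <- 0L
  for (f in seq_len(n_frames) - 1L) {
    img <- matrix(background, nr, nc)
    sel <- which(locs$frame == f)
    for (i in sel) {
      cx <- locs$x_um[i] / pixel_size
      cy <- locs$y_um[i] / pixel_size
      if (cx < 0 || cx > nc || cy < 0 || cy > nr) {
        clipped <- clipped + 1L
        next
      }
      # integrate the Gaussian over pixels within +/- 5 sigma
      j0 <- max(0L, floor(cx - 5 * s_px)); j1 <- min(nc - 1L, ceiling(cx + 5 * s_px))
      i0 <- max(0L, floor(cy - 5 * s_px)); i1 <- min(nr - 1L, ceiling(cy + 5 * s_px))
      if (j0 > j1 || i0 > i1) next
      px <- diff(stats::pnorm(seq(j0, j1 + 1L), mean = cx, sd = s_px))
      py <- diff(stats::pnorm(seq(i0, i1 + 1L), mean = cy, sd = s_px))
      img[(i0:i1) + 1L, (j0:j1) + 1L] <-
        img[(i0:i1) + 1L, (j0:j1) + 1L] +
        photons_per_frame * (py %o% px)
    }
    if (noise) {
      img <- matrix(stats::rpois(length(img), img), nr, nc)
    }
    frames[[f + 1L]] <- img
  }
  if (clipped > 0L) {
    warning(clipped, " emitter(s) outside the raster were clipped")
  }
  structure(list(frames = frames, pixel_size = pixel_size),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("frame_stack: %d frames of %dx%d px (pixel %.3g um)\n",
              length(x$frames), d[1L], d[2L], x$pixel_size))
  invisible(x)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Intensities are stored as 32-bit floats scaled to `[0, 1]` by the
#' recorded maximum, which is restored on reading.
#'
#' @param stack A `frame_stack`.
#' @param path Output file path.
#' @return `read_movie` returns a `frame_stack`.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  mx <- max(1e-12, vapply(stack$frames, max, numeric(1)))
  imgs <- lapply(stack$frames, function(f) f / mx)
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  scale_path <- paste0(path, ".scale")
  writeLines(c(format(mx, digits = 17), format(stack$pixel_size,
                                               digits = 17)), scale_path)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  scale_path <- paste0(path, ".scale")
  mx <- 1; px <- 0.096
  if (file.exists(scale_path)) {
    v <- as.numeric(readLines(scale_path))
    mx <- v[1L]; px <- v[2L]
  }
  structure(list(frames = lapply(imgs, function(f) f * mx),
                 pixel_size = px), class = "frame_stack")
}

#' Detect candidate emitters by band-pass filtering
#'
#' Band-passes each frame with a difference of Gaussians (small scale
#' passes single-molecule spots, large scale removes slowly varying
#' background), thresholds the filtered image, and reports one candidate —
#' the brightest pixel — per connected supra-threshold region.
#'
#' @param stack A `frame_stack`.
#' @param bandpass_low Small Gaussian sigma (px, default 1).
#' @param bandpass_high Large Gaussian sigma (px, default 4); must exceed
#'   `bandpass_low`.
#' @param threshold Intensity threshold on the band-passed image.
#' @return Data frame `frame` (0-based), `row_px`, `col_px` (0-based pixel
#'   indices of the candidate maximum).
#' @export
detect_candidates <- function(stack, bandpass_low = 1, bandpass_high = 4,
                              threshold) {
  stopifnot(inherits(stack, "frame_stack"), bandpass_low < bandpass_high)
  if (length(stack$frames) == 0L) stop("empty frame stack")
  out <- vector("list", length(stack$frames))
  for (f in seq_along(stack$frames)) {
    img <- stack$frames[[f]]
    bp <- dog_filter(img, bandpass_low, bandpass_high)
    mask <- bp > threshold
    if (!any(mask)) next
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(lab)
    cand <- lapply(seq_len(max(lab)), function(k) {
      idx <- which(lab == k)
      best <- idx[which.max(bp[idx])]
      rc <- arrayInd(best, dim(img))
      data.frame(frame = f - 1L, row_px = rc[1L] - 1L, col_px = rc[2L] - 1L)
    })
    out[[f]] <- do.call(rbind, cand)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(), row_px = integer(),
                      col_px = integer())
  }
  res
}

dog_filter <- function(img, s1, s2) {
  # replicate-pad so the Gaussian brush fits even on small rasters
  pad <- 2L * as.integer(ceiling(3 * s2)) + 2L
  ri <- c(rep(1L, pad), seq_len(nrow(img)), rep(nrow(img), pad))
  ci <- c(rep(1L, pad), seq_len(ncol(img)), rep(ncol(img), pad))
  big <- img[ri, ci]
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(big), sigma = s1)) -
    EBImage::imageData(EBImage::gblur(EBImage::Image(big), sigma = s2))
  sm[pad + seq_len(nrow(img)), pad + seq_len(ncol(img))]
}

#' Elliptical Gaussian localization
#'
#' Fits a two-dimensional elliptical Gaussian to a window around each
#' candidate by nonlinear least squares. Free parameters: x-position,
#' y-position, x-width, y-width, elliptical rotation angle, intensity, and
#' background. Initial center is the candidate pixel; initial widths come
#' from image moments. Non-converged fits are dropped and counted in the
#' `n_failed` attribute.
#'
#' For an isotropic PSF the rotation angle is unidentifiable; fits with
#' nearly equal widths are flagged in the `angle_identifiable` column.
#'
#' @param stack A `frame_stack`.
#' @param candidates Output of [detect_candidates()].
#' @param window Fit window side (px, odd, >= 5; default 9).
#' @return Localization table: `frame`, `x_um`, `y_um` plus fit
#'   descriptors (`width_x_um`, `width_y_um`, `angle_rad`, `intensity`,
#'   `background`, `angle_identifiable`); attribute `n_failed`.
#' @export
localize <- function(stack, candidates, window = 9L) {
  stopifnot(inherits(stack, "frame_stack"))
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L) stop("window must be odd and >= 5")
  half <- window %/% 2L
  px <- stack$pixel_size
  rows <- vector("list", nrow(candidates))
  n_failed <- 0L
  for (i in seq_len(nrow(candidates))) {
    fr <- candidates$frame[i] + 1L
    img <- stack$frames[[fr]]
    r0 <- candidates$row_px[i] + 1L
    c0 <- candidates$col_px[i] + 1L
    ri <- max(1L, r0 - half):min(nrow(img), r0 + half)
    ci <- max(1L, c0 - half):min(ncol(img), c0 + half)
    win <- img[ri, ci, drop = FALSE]
    fit <- fit_elliptical_gaussian(win, ri[1L], ci[1L])
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[i]] <- data.frame(
      frame = candidates$frame[i],
      x_um = fit$x_px * px, y_um = fit$y_px * px,
      width_x_um = fit$sx * px, width_y_um = fit$sy * px,
      angle_rad = fit$theta, intensity = fit$I, background = fit$bg,
      angle_identifiable = abs(fit$sx - fit$sy) >
        0.05 * max(fit$sx, fit$sy))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(frame = integer(), x_um = numeric(),
                      y_um = numeric())
  }
  attr(out, "n_failed") <- n_failed
  out
}

# Least-squares elliptical Gaussian fit on one window. row1/col1: 1-based
# origin of the window in the full image. Returns positions in continuous
# 0-based pixel coordinates (pixel centers at half-integers), or NULL if
# the optimizer fails.
fit_elliptical_gaussian <- function(win, row1, col1) {
  nr <- nrow(win); nc <- ncol(win)
  # pixel-center coordinates in the full image, 0-based convention
  xc <- (col1 - 1L):(col1 + nc - 2L) + 0.5
  yc <- (row1 - 1L):(row1 + nr - 2L) + 0.5
  X <- matrix(xc, nr, nc, byrow = TRUE)
  Y <- matrix(yc, nr, nc)
  bg0 <- min(win)
  w <- pmax(win - bg0, 0)
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  mx <- sum(X * w) / tot; my <- sum(Y * w) / tot
  sx0 <- sqrt(max(sum((X - mx)^2 * w) / tot, 0.25))
  sy0 <- sqrt(max(sum((Y - my)^2 * w) / tot, 0.25))
  p0 <- c(mx, my, log(sx0), log(sy0), 0, log(max(tot, 1)), bg0)
  model <- function(p) {
    sx <- exp(p[3L]); sy <- exp(p[4L]); th <- p[5L]
    dx <- X - p[1L]; dy <- Y - p[2L]
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    amp <- exp(p[6L]) / (2 * pi * sx * sy)
    p[7L] + amp * exp(-u^2 / (2 * sx^2) - v^2 / (2 * sy^2))
  }
  obj <- function(p) sum((model(p) - win)^2)
  fit <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  p <- fit$par
  sx <- exp(p[3L]); sy <- exp(p[4L])
  if (!is.finite(sx) || !is.finite(sy) || sx > nr || sy > nr) return(NULL)
  if (p[1L] < xc[1L] - 1 || p[1L] > xc[nc] + 1 ||
      p[2L] < yc[1L] - 1 || p[2L] > yc[nr] + 1) return(NULL)
  list(x_px = p[1L], y_px = p[2L], sx = sx, sy = sy,
       theta = p[5L] %% pi, I = exp(p[6L]), bg = p[7L])
}
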