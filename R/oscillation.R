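#' Build a kymograph from per-frame intensity profiles
#'
#' Stacks one-dimensional fluorescence profiles along the cell's long axis
#' into a space-time kymograph. Each frame is optionally normalized to its
#' total fluorescence, which removes photobleaching and any other
#' time-dependent global intensity factor.
#'
#' @param profiles Matrix (frames x positions) or list of equal-length
#'   numeric vectors.
#' @param times Frame times (s); length must match the number of frames.
#' @param length_um Cell length L spanned by the profiles (µm).
#' @param normalize Normalize each frame to unit total (default `TRUE`).
#' @return An object of class `kymograph`: list with `intensity` (frames x
#'   positions), `t` (s), `x` (µm, pixel centers over `[0, L]`),
#'   `length_um`, `normalized`.
#' @export
build_kymograph <- function(profiles, times, length_um,
                            normalize = TRUE) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1L) stop("ragged profiles")
    profiles <- do.call(rbind, profiles)
  }
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 4L) stop("need at least 4 frames")
  if (length(times) != nrow(profiles)) {
    stop("times must match the number of frames")
  }
  if (length_um <= 0) stop("cell length must be positive")
  if (normalize) {
    tot <- rowSums(profiles)
    if (any(tot <= 0)) stop("frames must have positive total intensity")
    profiles <- profiles / tot
  }
  nx <- ncol(profiles)
  structure(list(intensity = profiles, t = as.numeric(times),
                 x = (seq_len(nx) - 0.5) * length_um / nx,
                 length_um = length_um, normalized = normalize),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions over %.3g um\n",
              nrow(x$intensity), ncol(x$intensity), x$length_um))
  invisible(x)
}

#' Time-averaged axial concentration profile
#' @param k A `kymograph`.
#' @return Numeric vector, mean intensity per axial position.
#' @export
time_average_profile <- function(k) {
  stopifnot(inherits(k, "kymograph"))
  colMeans(k$intensity)
}

#' Integrated fluorescence of the two cell halves
#'
#' Integrates the kymograph intensity over `[0, L/2]` and `[L/2, L]` for
#' each frame. Pole-to-pole oscillations appear as anticorrelated
#' `F_left(t)` and `F_right(t)`; their sum is the total frame intensity.
#'
#' @param k A `kymograph`.
#' @return Data frame `t`, `F_left`, `F_right`.
#' @export
half_cell_signals <- function(k) {
  stopifnot(inherits(k, "kymograph"))
  nx <- ncol(k$intensity)
  half <- k$length_um / 2
  dx <- k$length_um / nx
  left_w <- pmax(pmin((half - (k$x - dx / 2)) / dx, 1), 0)
  F_left <- as.numeric(k$intensity %*% left_w)
  F_right <- rowSums(k$intensity) - F_left
  data.frame(t = k$t, F_left = F_left, F_right = F_right)
}

#' Fit the oscillation period of a half-cell trace
#'
#' Fits `F(t) = a cos(w t) + b sin(w t) + const` by a coarse scan over
#' angular frequency (periods 4-200 s by default) with the linear
#' coefficients solved exactly at each frequency, followed by local
#' refinement of the best frequency. The period is `T = 2 pi / w`. If the
#' fitted amplitude `sqrt(a^2 + b^2)` does not exceed `min_snr` times its
#' standard error, no oscillation is declared and an error of class
#' `tracksearch_no_oscillation` is thrown.
#'
#' @param trace Numeric vector F(t).
#' @param times Frame times (s).
#' @param period_range Search range for the period (s, default
#'   `c(4, 200)`).
#' @param min_snr Minimum amplitude / SE ratio to declare an oscillation
#'   (default 4; the frequency scan selects the best of many candidate
#'   frequencies, so pure noise can reach ~3 SE).
#' @return List with `period` (s), `omega` (rad/s), `a`, `b`,
#'   `amplitude`, `phase`.
#' @export
fit_period <- function(trace, times, period_range = c(4, 200),
                       min_snr = 4) {
  stopifnot(length(trace) == length(times), length(trace) >= 8L)
  span <- diff(range(times))
  if (span <= 0) stop("times must span a positive interval")
  p_hi <- min(period_range[2L], span / 2)  # need >= 2 putative periods
  p_lo <- max(period_range[1L], 2.5 * stats::median(diff(sort(times))))
  if (p_hi <= p_lo) stop("time series too short for the period range")
  w_grid <- 2 * pi / seq(p_hi, p_lo, length.out = 800L)
  rss <- function(w) {
    X <- cbind(1, cos(w * times), sin(w * times))
    f <- stats::lm.fit(X, trace)
    sum(f$residuals^2)
  }
  r <- vapply(w_grid, rss, numeric(1))
  i <- which.min(r)
  lo <- w_grid[max(1L, i - 1L)]; hi <- w_grid[min(length(w_grid), i + 1L)]
  opt <- stats::optimize(rss, lower = min(lo, hi), upper = max(lo, hi))
  w <- opt$minimum
  X <- cbind(1, cos(w * times), sin(w * times))
  f <- stats::lm.fit(X, trace)
  a <- f$coefficients[2L]; b <- f$coefficients[3L]
  n <- length(trace)
  sigma2 <- sum(f$residuals^2) / max(1L, n - 3L)
  # each of a, b has variance ~ 2 sigma^2 / n for a sinusoid design
  se_amp <- sqrt(2 * sigma2 / n)
  amp <- sqrt(a^2 + b^2)
  if (!is.finite(amp) || amp < min_snr * se_amp) {
    stop(structure(class = c("tracksearch_no_oscillation", "error",
                             "condition"),
                   list(message = "no significant oscillation detected",
                        call = sys.call(-1))))
  }
  list(period = 2 * pi / w, omega = w, a = unname(a), b = unname(b),
       amplitude = amp, phase = atan2(-b, a))
}

#' Oscillation wavelength from the time-averaged profile
#'
#' For filamentous cells sustaining a standing wave with several nodes,
#' the wavelength is the mean spacing of consecutive minima of the
#' time-averaged axial profile; in peak mode it is the mean spacing of
#' consecutive maxima. The profile is lightly smoothed (running mean)
#' before extrema detection.
#'
#' @param k A `kymograph`.
#' @param filamentous Use minima spacing (default `TRUE`); otherwise peak
#'   spacing.
#' @param smooth Running-mean half-width in profile samples (default 2; 0
#'   disables smoothing).
#' @param min_depth Minimum depth of an extremum as a fraction of the
#'   profile range (default 0.5): only minima in the lower half of the
#'   range (or peaks in the upper half) count, which rejects noise
#'   wiggles riding on the crests.
#' @return Wavelength (µm).
#' @export
wavelength_from_profile <- function(k, filamentous = TRUE, smooth = 2L,
                                    min_depth = 0.5) {
  stopifnot(inherits(k, "kymograph"))
  p <- time_average_profile(k)
  if (smooth > 0L) {
    kern <- rep(1, 2L * smooth + 1L) / (2L * smooth + 1L)
    p <- as.numeric(stats::filter(p, kern, sides = 2))
    keep <- !is.na(p)
    p <- p[keep]; x <- k$x[keep]
  } else {
    x <- k$x
  }
  n <- length(p)
  if (n < 5L) stop("profile too short for extrema detection")
  # invert for minima so both modes reduce to peak finding
  v <- if (filamentous) max(p) - p else p - min(p)
  rng <- diff(range(v))
  if (rng <= 0) stop("insufficient extrema to measure a wavelength")
  pk <- pracma::findpeaks(v, minpeakheight = min_depth * max(v),
                          minpeakdistance = max(3L, round(n / 25)))
  if (is.null(pk) || nrow(pk) < 2L) {
    stop("insufficient extrema to measure a wavelength")
  }
  mean(diff(sort(x[pk[, 2L]])))
}
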