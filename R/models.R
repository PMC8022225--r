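#' Physical motion model for a tracked molecule
#'
#' Ground-truth parameters of the two-state diffusion model: a molecule is
#' either freely diffusing (`D_free`) or DNA-bound (`D_bound`, reflecting
#' the slow constrained motion of chromosomal DNA), and interconverts with
#' exponential dwell times. The bound-time fraction
#' `phi = mean_t_bound / (mean_t_bound + mean_t_free)` parameterizes the
#' stationary occupancy of the bound state; only the ratio of dwell times
#' is identifiable from camera-limited tracking, not their absolute
#' durations.
#'
#' @param D_free Free diffusion coefficient (µm²/s).
#' @param D_bound Diffusion coefficient in the DNA-bound state (µm²/s,
#'   default 0.04).
#' @param switching Logical; if `FALSE` the molecule stays in the free
#'   state for its whole trajectory.
#' @param phi Bound-time fraction in `[0, 1]`; required when `switching`.
#' @param mean_t_bound Mean bound dwell time (s, default 0.001).
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(D_free, D_bound = 0.04, switching = FALSE,
                         phi = NULL, mean_t_bound = 0.001) {
  if (!is.numeric(D_free) || D_free < 0) stop("D_free must be >= 0")
  if (!is.numeric(D_bound) || D_bound < 0) stop("D_bound must be >= 0")
  if (D_bound > D_free) stop("require D_free >= D_bound >= 0")
  if (switching) {
    if (is.null(phi)) stop("phi is required when switching is enabled")
    if (!is.numeric(phi) || phi < 0 || phi > 1) stop("phi must be in [0, 1]")
    if (mean_t_bound <= 0) stop("mean_t_bound must be > 0")
  }
  structure(list(D_free = D_free, D_bound = D_bound, switching = switching,
                 phi = if (switching) phi else NA_real_,
                 mean_t_bound = mean_t_bound),
            class = "motion_model")
}

#' Camera and photophysics model
#'
#' Acquisition parameters of photoactivated single-molecule tracking:
#' frame interval, sub-frame discretization used to model motion blur over
#' the continuous exposure, Gaussian localization error, exponential
#' photobleaching lifetime, movie length, and pixel size.
#'
#' @param frame_interval Time between frames (s, default 0.01548: 15 ms
#'   exposure plus 0.48 ms readout).
#' @param n_subframes Sub-frames per frame used to model motion blur
#'   (default 100).
#' @param sigma_loc Localization error SD per coordinate (µm, default
#'   0.035).
#' @param bleach_mean Mean photobleaching lifetime (s, default 0.085).
#' @param movie_frames Number of frames in the movie (default 1000).
#' @param pixel_size Camera pixel size (µm, default 0.096).
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(frame_interval = 0.01548, n_subframes = 100L,
                              sigma_loc = 0.035, bleach_mean = 0.085,
                              movie_frames = 1000L, pixel_size = 0.096) {
  vals <- c(frame_interval = frame_interval, sigma_loc = sigma_loc,
            bleach_mean = bleach_mean, pixel_size = pixel_size)
  if (any(!is.finite(vals)) || frame_interval <= 0 || bleach_mean <= 0 ||
      pixel_size <= 0 || sigma_loc < 0) {
    stop("acquisition parameters must be positive (sigma_loc may be 0)")
  }
  n_subframes <- as.integer(n_subframes)
  movie_frames <- as.integer(movie_frames)
  if (n_subframes < 1L) stop("n_subframes must be >= 1")
  if (movie_frames < 1L) stop("movie_frames must be >= 1")
  structure(list(frame_interval = frame_interval, n_subframes = n_subframes,
                 sigma_loc = sigma_loc, bleach_mean = bleach_mean,
                 movie_frames = movie_frames, pixel_size = pixel_size),
            class = "acquisition_model")
}

#' @export
print.motion_model <- function(x, ...) {
  if (x$switching) {
    cat(sprintf(
      "motion_model: D_free %.3g, D_bound %.3g um^2/s, phi %.3g, t_bound %.3g s\n",
      x$D_free, x$D_bound, x$phi, x$mean_t_bound))
  } else {
    cat(sprintf("motion_model: D_free %.3g um^2/s (no state switching)\n",
                x$D_free))
  }
  invisible(x)
}

#' @export
print.acquisition_model <- function(x, ...) {
  cat(sprintf(
    "acquisition_model: dt %.4g s, %d sub-frames, sigma_loc %.3g um, bleach %.3g s\n",
    x$frame_interval, x$n_subframes, x$sigma_loc, x$bleach_mean))
  invisible(x)
}
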