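#' Simulation-matching estimate of the unbiased diffusion coefficient
#'
#' Apparent diffusion coefficients from camera-limited tracking are biased
#' by confinement in the cell volume, motion blur, and localization error.
#' This removes the bias by simulation matching: for each candidate D on a
#' grid, molecules are simulated in the supplied cell volumes under the
#' identical acquisition model, the simulated and observed D* histograms
#' are compared by least squares on shared bins, and the best-matching D is
#' returned with parabolic refinement around the grid minimum.
#'
#' @param observed A `dstar_sample` or numeric vector of observed D*
#'   values (µm²/s).
#' @param geoms List of [cell_geometry()] (e.g.
#'   [default_cell_population()]).
#' @param acq An [acquisition_model()].
#' @param d_grid Candidate D values (µm²/s; default 0 to 10 by 0.05).
#' @param seed Integer seed.
#' @param n_sim Simulated molecules per grid point (default 10x the
#'   observed track count, to suppress grid-point noise).
#' @param bins Histogram bin edges (µm²/s; default 0.05-wide over
#'   `[0, 10]`). Values above the top edge are pooled into the last bin.
#' @param n_steps Steps per track (default 4).
#' @return A list of class `grid_match` with `D` (refined estimate),
#'   `grid` (data frame of candidate D and least-squares score), and
#'   `D_grid_best` (unrefined argmin).
#' @export
match_unbiased_D <- function(observed, geoms, acq,
                             d_grid = seq(0, 10, by = 0.05), seed = 1L,
                             n_sim = NULL, bins = seq(0, 10, by = 0.05),
                             n_steps = 4L) {
  obs <- dstar_values(observed)
  if (length(obs) < 1L) stop("empty observation")
  if (length(d_grid) < 3L || any(diff(d_grid) <= 0)) {
    stop("d_grid must be an increasing grid with >= 3 points")
  }
  stopifnot(inherits(acq, "acquisition_model"), length(geoms) >= 1L)
  if (is.null(n_sim)) n_sim <- 10L * length(obs)
  h_obs <- bin_fractions(obs, bins)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  score <- vapply(d_grid, function(D) {
    motion <- motion_model(D_free = max(D, 1e-9), D_bound = 0)
    v <- sim_dstar_population(motion, acq, geoms, n_sim, n_steps = n_steps)
    if (length(v) == 0L) return(Inf)
    sum((bin_fractions(v, bins) - h_obs)^2)
  }, numeric(1))
  i <- which.min(score)
  D_best <- d_grid[i]
  D_ref <- parabolic_min(d_grid, score, i)
  structure(list(D = D_ref, D_grid_best = D_best,
                 grid = data.frame(D = d_grid, score = score)),
            class = "grid_match")
}

bin_fractions <- function(x, bins) {
  x <- pmin(pmax(x, bins[1L]), bins[length(bins)] - 1e-12)
  counts <- tabulate(findInterval(x, bins, rightmost.closed = TRUE),
                     nbins = length(bins) - 1L)
  counts / sum(counts)
}

parabolic_min <- function(x, y, i) {
  if (i <= 1L || i >= length(x) || !all(is.finite(y[(i - 1L):(i + 1L)]))) {
    return(x[i])
  }
  x0 <- x[i]; h1 <- x[i] - x[i - 1L]; h2 <- x[i + 1L] - x[i]
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- h2 * (y1 - y2) + h1 * (y3 - y2)
  if (denom <= 0) return(x0)
  x0 + (h2^2 * (y1 - y2) - h1^2 * (y3 - y2)) / (2 * denom)
}

#' Estimate the transiently DNA-bound time fraction
#'
#' During the target search, mobile DNA-binding proteins rapidly
#' interconvert between free 3D diffusion (`D_free`, measured in
#' chromosome-free cells) and transient non-specific DNA binding
#' (`D_bound`). The fraction of time spent bound, `phi`, is estimated by
#' simulation matching: over a grid of `phi` values, interconverting
#' molecules (bound dwell ~ Exp(`mean_t_bound`), free dwell set by the
#' ratio) are simulated in the supplied cell volumes with the full
#' acquisition model, the mobile-species apparent coefficient is fitted to
#' each simulated D* distribution, and the `phi` whose fitted D* is
#' closest to the observed target is returned with linear interpolation
#' between the bracketing grid points.
#'
#' @param D_free Free diffusion coefficient (µm²/s).
#' @param target_dstar_mobile Observed apparent D* of the mobile
#'   population (µm²/s), from the two-species fit of the unperturbed-cell
#'   D* distribution.
#' @param acq An [acquisition_model()].
#' @param geoms List of [cell_geometry()]; default
#'   [default_cell_population()].
#' @param D_bound Bound-state diffusion coefficient (µm²/s, default 0.04).
#' @param mean_t_bound Mean transient bound dwell (s, default 0.001). Only
#'   the bound:free time ratio is identifiable; this sets the timescale.
#' @param phi_grid Grid of bound-time fractions (default 0 to 1 by 0.01).
#' @param n_tracks Simulated molecules per grid point (default 10000).
#' @param seed Integer seed.
#' @return A list of class `phi_estimate` with `phi` (interpolated
#'   estimate), `grid` (data frame of phi and fitted D*), and the target.
#' @export
estimate_phi <- function(D_free, target_dstar_mobile, acq,
                         geoms = default_cell_population(),
                         D_bound = 0.04, mean_t_bound = 0.001,
                         phi_grid = seq(0, 1, by = 0.01),
                         n_tracks = 10000L, seed = 1L) {
  stopifnot(D_free > D_bound, inherits(acq, "acquisition_model"))
  if (any(phi_grid < 0 | phi_grid > 1) || any(diff(phi_grid) <= 0)) {
    stop("phi_grid must be increasing within [0, 1]")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  fitted <- vapply(phi_grid, function(phi) {
    motion <- motion_model(D_free = D_free, D_bound = D_bound,
                           switching = TRUE, phi = phi,
                           mean_t_bound = mean_t_bound)
    v <- sim_dstar_population(motion, acq, geoms, n_tracks)
    # single mobile species: the Gamma-model MLE is the sample mean
    mean(v)
  }, numeric(1))
  lo <- min(fitted); hi <- max(fitted)
  if (target_dstar_mobile < lo - 1e-9 || target_dstar_mobile > hi + 1e-9) {
    stop(sprintf(
      "target D* (%.3g) outside the achievable range [%.3g, %.3g] for this D_free",
      target_dstar_mobile, lo, hi))
  }
  # fitted D* decreases monotonically with phi (up to simulation noise);
  # interpolate the crossing around the closest grid point
  i <- which.min(abs(fitted - target_dstar_mobile))
  phi_hat <- phi_grid[i]
  j <- if (i < length(phi_grid) &&
           sign(fitted[i] - target_dstar_mobile) !=
           sign(fitted[min(i + 1L, length(fitted))] - target_dstar_mobile)) {
    i + 1L
  } else if (i > 1L &&
             sign(fitted[i] - target_dstar_mobile) !=
             sign(fitted[i - 1L] - target_dstar_mobile)) {
    i - 1L
  } else NA_integer_
  if (!is.na(j) && fitted[j] != fitted[i]) {
    w <- (target_dstar_mobile - fitted[i]) / (fitted[j] - fitted[i])
    phi_hat <- phi_grid[i] + w * (phi_grid[j] - phi_grid[i])
  }
  structure(list(phi = phi_hat, target = target_dstar_mobile,
                 grid = data.frame(phi = phi_grid, dstar_fitted = fitted)),
            class = "phi_estimate")
}

#' @export
print.phi_estimate <- function(x, ...) {
  cat(sprintf("phi_estimate: phi = %.3f (target D* = %.3g um^2/s)\n",
              x$phi, x$target))
  invisible(x)
}

#' Three-state partitioning of DNA-binding protein activity
#'
#' Splits a protein population into long-lived DNA-bound molecules (at
#' specific target sites), transiently DNA-bound molecules, and freely
#' diffusing molecules, from the long-lived immobile fraction `A` (mixture
#' fit of the D* distribution) and the transiently bound time fraction
#' `phi` of the mobile molecules:
#' long-lived = `100 A`, transient = `100 phi (1 - A)`,
#' free = `100 (1 - phi)(1 - A)`.
#'
#' @param A_immobile Long-lived immobile fraction in `[0, 1]`.
#' @param phi Transiently bound time fraction in `[0, 1]`.
#' @return A named numeric vector of percentages (`pct_long_lived`,
#'   `pct_transient`, `pct_free`), summing to 100.
#' @examples
#' partition_states(0.45, 0.87)  # RNA polymerase: ~(45, 48, 7)
#' @export
partition_states <- function(A_immobile, phi) {
  check_fraction(A_immobile, "A_immobile")
  check_fraction(phi, "phi")
  c(pct_long_lived = 100 * A_immobile,
    pct_transient = 100 * phi * (1 - A_immobile),
    pct_free = 100 * (1 - phi) * (1 - A_immobile))
}

#' Total DNA-bound percentage
#'
#' Percentage of molecules bound to DNA at any instant: long-lived
#' target-site binding plus transient non-specific binding,
#' `100 (A + phi (1 - A))`.
#'
#' @inheritParams partition_states
#' @return Percentage in `[0, 100]`.
#' @examples
#' total_bound(0.41, 0.93)  # LacI: ~96
#' @export
total_bound <- function(A_immobile, phi) {
  check_fraction(A_immobile, "A_immobile")
  check_fraction(phi, "phi")
  100 * (A_immobile + phi * (1 - A_immobile))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be in [0, 1]")
  }
  invisible(TRUE)
}
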