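#' Apparent diffusion coefficient of a single track
#'
#' Computes the per-track apparent diffusion coefficient from the one-step
#' mean-squared displacement of the first `n_steps` steps:
#' \deqn{D_i^* = \frac{1}{4 n \Delta t} \sum_{k=1}^{n}
#'   (x_{k+1}-x_k)^2 + (y_{k+1}-y_k)^2}
#' Longer tracks are truncated after the (`n_steps`+1)-th localization, so
#' every track contributes the same number of steps. Steps spanning a gap
#' (memory link) cover more than one frame interval and would bias the
#' one-step MSD, so the first `n_steps` steps must be between consecutive
#' frames or the track is rejected.
#'
#' @param track Data frame with columns `frame`, `x_um`, `y_um` (one
#'   track, sorted by frame).
#' @param frame_interval Frame interval \eqn{\Delta t} (s).
#' @param n_steps Number of one-frame steps (default 4).
#' @return The apparent diffusion coefficient (µm²/s), or `NA` if the
#'   track is too short or its first steps are gap-broken.
#' @export
track_dstar <- function(track, frame_interval, n_steps = 4L) {
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 1L, frame_interval > 0)
  if (nrow(track) < n_steps + 1L) return(NA_real_)
  o <- order(track$frame)
  f <- track$frame[o][seq_len(n_steps + 1L)]
  if (any(diff(f) != 1L)) return(NA_real_)
  x <- track$x_um[o][seq_len(n_steps + 1L)]
  y <- track$y_um[o][seq_len(n_steps + 1L)]
  sum(diff(x)^2 + diff(y)^2) / (4 * n_steps * frame_interval)
}

#' Apparent diffusion coefficients for a table of tracks
#'
#' Applies [track_dstar()] to every track in a linked-track table and
#' returns one row per accepted track. Rejected tracks (too short, or with
#' a gap among the first `n_steps` steps) are counted.
#'
#' @param tracks Data frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um` and optionally `cell_id`.
#' @param frame_interval Frame interval (s).
#' @param n_steps Number of steps (default 4).
#' @return An object of class `dstar_sample`: data frame with columns
#'   `track_id`, `cell_id`, `dstar`, plus attributes `n_steps`,
#'   `frame_interval` and `n_rejected`.
#' @export
dstar_sample <- function(tracks, frame_interval, n_steps = 4L) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  if (!"cell_id" %in% names(tracks)) tracks$cell_id <- 1L
  o <- order(tracks$track_id, tracks$frame)
  tr <- tracks[o, ]
  idx <- split(seq_len(nrow(tr)), tr$track_id)
  n_steps <- as.integer(n_steps)
  vals <- vapply(idx, function(i) {
    k <- i[seq_len(min(length(i), n_steps + 1L))]
    if (length(k) < n_steps + 1L) return(NA_real_)
    f <- tr$frame[k]
    if (any(diff(f) != 1L)) return(NA_real_)
    sum(diff(tr$x_um[k])^2 + diff(tr$y_um[k])^2) /
      (4 * n_steps * frame_interval)
  }, numeric(1))
  cells <- vapply(idx, function(i) tr$cell_id[i[1L]], tr$cell_id[1L])
  keep <- !is.na(vals)
  out <- data.frame(track_id = names(idx)[keep],
                    cell_id = cells[keep],
                    dstar = unname(vals[keep]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("dstar_sample", "data.frame"),
            n_steps = n_steps, frame_interval = frame_interval,
            n_rejected = sum(!keep))
}

as_dstar_sample <- function(values, cell_id = 1L, n_steps = 4L,
                            frame_interval = 0.01548) {
  structure(
    data.frame(track_id = as.character(seq_along(values)),
               cell_id = rep_len(cell_id, length(values)),
               dstar = as.numeric(values), stringsAsFactors = FALSE),
    class = c("dstar_sample", "data.frame"),
    n_steps = as.integer(n_steps), frame_interval = frame_interval,
    n_rejected = 0L)
}

#' Sampling density of the apparent diffusion coefficient
#'
#' For a molecule diffusing with apparent coefficient `D` and tracked over
#' `n` one-frame steps, the apparent coefficient \eqn{D_i^*} follows
#' \deqn{p(D_i^*) = \frac{1}{(n-1)!} \left(\frac{n}{D}\right)^n
#'   (D_i^*)^{n-1} e^{-n D_i^*/D},}
#' a Gamma density with shape `n` and mean `D` (each of the `2n` squared
#' displacement components is an independent chi-square contribution).
#'
#' @param x Apparent diffusion coefficient values (µm²/s, >= 0).
#' @param D Underlying apparent diffusion coefficient (µm²/s, > 0).
#' @param n Number of steps per track (default 4).
#' @return Density values.
#' @examples
#' dstar_pdf(1, D = 1, n = 4)  # 256 exp(-4) / 6
#' @export
dstar_pdf <- function(x, D, n = 4L) {
  if (!is.numeric(D) || any(D <= 0)) stop("D must be positive")
  if (n < 1) stop("n must be >= 1")
  stats::dgamma(x, shape = n, rate = n / D)
}

#' Single-species fit of a D* sample
#'
#' Maximum-likelihood estimate of the apparent diffusion coefficient under
#' the model of [dstar_pdf()]; for this Gamma family the MLE is the sample
#' mean. The confidence interval comes from the exact Gamma sampling
#' distribution of the mean (shape `n * N`).
#'
#' @param sample A `dstar_sample` (or numeric vector of D* values).
#' @param conf Confidence level (default 0.95).
#' @return A list with `D` (point estimate), `ci` (length-2 vector),
#'   `n_tracks` and `loglik`.
#' @export
fit_single <- function(sample, conf = 0.95) {
  v <- dstar_values(sample)
  if (length(v) < 1L) stop("empty sample")
  if (all(v == 0)) stop("degenerate all-zero sample")
  n <- dstar_nsteps(sample)
  D <- mean(v)
  shape <- n * length(v)
  a <- (1 - conf) / 2
  # mean ~ Gamma(shape, rate = shape / D_true): invert for D_true
  ci <- shape * D / stats::qgamma(c(1 - a, a), shape = shape)
  list(D = D, ci = sort(unname(ci)), n_tracks = length(v),
       loglik = sum(log(dstar_pdf(pmax(v, 1e-12), D, n))))
}

#' Two-species mixture fit of a D* distribution
#'
#' Fits the D* sample with a mixture of two molecular species — long-lived
#' immobile molecules bound to DNA for the whole trajectory, and mobile
#' molecules searching for targets — each following the Gamma sampling
#' density of [dstar_pdf()]:
#' \deqn{p(D_i^*) = A\, p(D_i^* ; D_1^*) + (1-A)\, p(D_i^* ; D_2^*)}
#' by maximum likelihood with multi-start bounded optimization. Components
#' are ordered so `D1 <= D2`; `A` is the immobile fraction.
#'
#' @param sample A `dstar_sample` or numeric vector of D* values.
#' @param n_starts Number of random multi-starts (default 10).
#' @param seed Seed for the random starts (default 1).
#' @param bounds_D Bounds for both diffusion coefficients
#'   (default `c(1e-3, 20)`).
#' @return An object of class `mixture_fit`: list with `A`, `D1`, `D2`,
#'   `loglik`, `se` (delta-method standard errors), `ci` (2x3 matrix of
#'   Wald 95% intervals), `n_tracks`, `convergence`.
#' @export
fit_mixture <- function(sample, n_starts = 10L, seed = 1L,
                        bounds_D = c(1e-3, 20)) {
  v <- dstar_values(sample)
  if (length(v) < 10L) stop("too few D* values for a mixture fit")
  n <- dstar_nsteps(sample)
  v <- pmax(v, 1e-12)
  nll <- function(p) {
    A <- p[1L]; d1 <- p[2L]; d2 <- p[3L]
    f <- A * dstar_pdf(v, d1, n) + (1 - A) * dstar_pdf(v, d2, n)
    -sum(log(pmax(f, 1e-300)))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  qs <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9))
  starts <- list(c(0.5, qs[[1L]], qs[[5L]]), c(0.3, qs[[2L]], qs[[4L]]))
  for (i in seq_len(max(0L, n_starts - 2L))) {
    starts[[length(starts) + 1L]] <-
      c(stats::runif(1, 0.05, 0.95),
        exp(stats::runif(1, log(max(bounds_D[1L], 1e-3)), log(qs[[3L]] + 1e-6))),
        exp(stats::runif(1, log(qs[[3L]] + 1e-6), log(bounds_D[2L]))))
  }
  lower <- c(0, bounds_D[1L], bounds_D[1L])
  upper <- c(1, bounds_D[2L], bounds_D[2L])
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("mixture fit failed to converge from any start")
  p <- best$par
  if (p[2L] > p[3L]) p <- c(1 - p[1L], p[3L], p[2L])
  se <- rep(NA_real_, 3L)
  H <- tryCatch(stats::optimHess(p, nll), error = function(e) NULL)
  if (!is.null(H)) {
    cv <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  ci <- rbind(p - 1.96 * se, p + 1.96 * se)
  ci[1L, ] <- pmax(ci[1L, ], c(0, 0, 0))
  ci[2L, 1L] <- min(ci[2L, 1L], 1)
  colnames(ci) <- c("A", "D1", "D2")
  structure(list(A = p[1L], D1 = p[2L], D2 = p[3L], loglik = -best$value,
                 se = stats::setNames(se, c("A", "D1", "D2")), ci = ci,
                 n_tracks = length(v), convergence = best$convergence),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit: A = %.3f (immobile), D1* = %.3f, D2* = %.3f um^2/s, logL = %.1f (n = %d)\n",
    x$A, x$D1, x$D2, x$loglik, x$n_tracks))
  invisible(x)
}

#' Cell-level bootstrap confidence intervals
#'
#' Resamples segmented cells with replacement, pools the tracks of the
#' sampled cells, refits, and returns percentile confidence intervals.
#' Resampling whole cells (rather than tracks) respects the correlation of
#' tracks within a cell.
#'
#' @param sample A `dstar_sample` with at least two distinct `cell_id`s.
#' @param fit_kind `"single"` or `"mixture"`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A list with `estimate` (full-sample fit parameters), `ci`
#'   (matrix with 2 rows, lower/upper), and `replicates` (matrix of
#'   per-replicate parameters).
#' @export
bootstrap_cells <- function(sample, fit_kind = c("single", "mixture"),
                            n_boot = 1000L, seed = 1L, conf = 0.95) {
  fit_kind <- match.arg(fit_kind)
  stopifnot(inherits(sample, "dstar_sample"))
  cells <- unique(sample$cell_id)
  if (length(cells) < 2L) {
    stop("cell-level bootstrap needs at least two distinct cells")
  }
  by_cell <- split(sample$dstar, sample$cell_id)
  n_steps <- dstar_nsteps(sample)
  dt <- attr(sample, "frame_interval")
  stat <- function(vals) {
    s <- as_dstar_sample(vals, n_steps = n_steps, frame_interval = dt)
    if (fit_kind == "single") {
      c(D = fit_single(s)$D)
    } else {
      f <- fit_mixture(s)
      c(A = f$A, D1 = f$D1, D2 = f$D2)
    }
  }
  est <- stat(sample$dstar)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(est),
                 dimnames = list(NULL, names(est)))
  ids <- names(by_cell)
  for (b in seq_len(n_boot)) {
    take <- sample.int(length(ids), length(ids), replace = TRUE)
    vals <- unlist(by_cell[take], use.names = FALSE)
    reps[b, ] <- tryCatch(stat(vals), error = function(e) NA_real_)
  }
  a <- (1 - conf) / 2
  ci <- apply(reps, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  list(estimate = est, ci = ci, replicates = reps)
}

#' Classify tracks as immobile or mobile
#'
#' Labels each track by comparing its apparent diffusion coefficient to a
#' fixed threshold (default 0.15 µm²/s, separating long-lived DNA-bound
#' molecules from searching ones). Values exactly at the threshold are
#' labeled mobile.
#'
#' @param sample A `dstar_sample` or numeric vector of D* values.
#' @param threshold Classification threshold (µm²/s, default 0.15).
#' @return A factor with levels `immobile`, `mobile`.
#' @export
classify_tracks <- function(sample, threshold = 0.15) {
  v <- dstar_values(sample)
  factor(ifelse(v < threshold, "immobile", "mobile"),
         levels = c("immobile", "mobile"))
}

#' Correct an apparent diffusion coefficient for localization error
#'
#' Localization noise adds a positive offset of `sigma_loc^2 / dt` to
#' apparent diffusion coefficients. `offset_correct` subtracts the
#' theoretical offset; `baseline_correct` subtracts an empirically measured
#' baseline (e.g. the apparent D* of molecules in chemically fixed cells),
#' which additionally absorbs residual motion of the "immobile" reference.
#' Both floor the result at zero.
#'
#' @param D_star Apparent diffusion coefficient (µm²/s).
#' @param sigma_loc Localization error SD (µm).
#' @param frame_interval Frame interval (s).
#' @return Corrected coefficient (µm²/s).
#' @examples
#' offset_correct(0.11, 0.035, 0.01548)   # ~0.031
#' baseline_correct(0.11, 0.07)           # 0.04
#' @export
offset_correct <- function(D_star, sigma_loc, frame_interval) {
  stopifnot(D_star >= 0, sigma_loc >= 0, frame_interval > 0)
  pmax(D_star - sigma_loc^2 / frame_interval, 0)
}

#' @rdname offset_correct
#' @param baseline Empirical apparent D* of a fixed (immobile) reference
#'   (µm²/s, default 0.07).
#' @export
baseline_correct <- function(D_star, baseline = 0.07) {
  stopifnot(D_star >= 0, baseline >= 0)
  pmax(D_star - baseline, 0)
}

dstar_values <- function(sample) {
  if (inherits(sample, "dstar_sample")) sample$dstar else as.numeric(sample)
}

dstar_nsteps <- function(sample) {
  n <- attr(sample, "n_steps")
  if (is.null(n)) 4L else n
}
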