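#' Simulate confined single-molecule tracks
#'
#' Monte Carlo simulation of molecules undergoing Brownian motion confined
#' to a 3D cell volume, with optional two-state (bound/free)
#' interconversion. Each frame is split into `acq$n_subframes` sub-frames
#' with isotropic Gaussian displacements (per-axis variance `2 D dt_sub`,
#' `D` being the coefficient of the state occupied at the sub-frame start);
#' confinement is enforced by specular reflection at the cell wall. The
#' observed frame position is the mean of the frame's sub-frame (x, y)
#' positions — reproducing motion blur over the continuous exposure — plus
#' independent Gaussian localization noise. Molecules photoactivate at a
#' uniformly random frame and bleach after an exponential lifetime;
#' molecules bleaching mid-frame contribute only their completed frames.
#'
#' @param motion A [motion_model()].
#' @param acq An [acquisition_model()].
#' @param geom A [cell_geometry()].
#' @param n_molecules Number of molecules to simulate.
#' @param seed Integer seed; identical seeds give identical output.
#' @param cell_id Cell identifier attached to the localization table.
#' @param max_frames Cap on observed frames per molecule (default
#'   unlimited). Tracks are truncated to their first 5 localizations by the
#'   D* analysis anyway, so inference loops cap at 5 to save time.
#' @param keep_truth If `TRUE`, also return ground-truth sub-frame 3D
#'   positions and state labels (memory-heavy; meant for small runs).
#' @return A list with elements `localizations` (data frame `frame`,
#'   `x_um`, `y_um`, `cell_id`, `track_id`), `meta` (per-molecule
#'   activation frame, observed frame count, bleach duration, fraction of
#'   sub-frames spent bound), and, when `keep_truth`, `subframe`
#'   (per-sub-frame 3D positions and state).
#' @examples
#' geom <- make_spherocylinder(3, 0.45)
#' sim <- simulate_tracks(motion_model(D_free = 1), acquisition_model(),
#'                        geom, n_molecules = 10, seed = 1)
#' head(sim$localizations)
#' @export
simulate_tracks <- function(motion, acq, geom, n_molecules, seed,
                            cell_id = 1L, max_frames = Inf,
                            keep_truth = FALSE) {
  stopifnot(inherits(motion, "motion_model"),
            inherits(acq, "acquisition_model"),
            inherits(geom, "cell_geometry"))
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    stop("n_molecules must be >= 1")
  }
  check_seed(seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  res <- sim_raw(motion, acq, geom, n_molecules,
                 max_frames = max_frames, keep_truth = keep_truth,
                 dstar_only = FALSE)
  locs <- res$localizations
  locs$cell_id <- rep(cell_id, nrow(locs))
  names(locs)[names(locs) == "molecule"] <- "track_id"
  res$localizations <- locs[, c("frame", "x_um", "y_um", "cell_id",
                                "track_id")]
  res
}

# Thin wrapper over the compiled core; assumes the RNG is already seeded.
sim_raw <- function(motion, acq, geom, n_molecules, max_frames = Inf,
                    keep_truth = FALSE, dstar_only = FALSE,
                    n_dstar_steps = 4L) {
  mx <- if (is.finite(max_frames)) as.integer(max_frames) else
    acq$movie_frames
  .sim_tracks_cpp(geom$axial_start_um, geom$axial_end_um, geom$radius_um,
                  as.integer(n_molecules), motion$D_free, motion$D_bound,
                  motion$switching,
                  if (is.na(motion$phi)) 0 else motion$phi,
                  motion$mean_t_bound, acq$frame_interval,
                  acq$n_subframes, acq$sigma_loc, acq$bleach_mean,
                  acq$movie_frames, mx, keep_truth, dstar_only,
                  as.integer(n_dstar_steps))
}

# Fast path for simulation-matching: per-molecule apparent diffusion
# coefficients from the first `n_steps` consecutive steps, computed inside
# the compiled core (identical to track_dstar on the localization table,
# which is asserted by a test). NA for molecules observed < n_steps+1
# frames. Assumes the RNG is already seeded by the caller.
sim_dstar <- function(motion, acq, geom, n_molecules, n_steps = 4L) {
  res <- sim_raw(motion, acq, geom, n_molecules,
                 max_frames = n_steps + 1L, dstar_only = TRUE,
                 n_dstar_steps = n_steps)
  res$dstar
}

# Simulate across a population of cell geometries, molecules split as
# evenly as possible; returns the pooled D* vector (NAs dropped).
sim_dstar_population <- function(motion, acq, geoms, n_molecules,
                                 n_steps = 4L) {
  n_cells <- length(geoms)
  per <- diff(round(seq(0, n_molecules, length.out = n_cells + 1L)))
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    if (per[i] > 0L) {
      out[[i]] <- sim_dstar(motion, acq, geoms[[i]], per[i],
                            n_steps = n_steps)
    }
  }
  v <- unlist(out, use.names = FALSE)
  v[!is.na(v)]
}

check_seed <- function(seed) {
  if (missing(seed) || length(seed) != 1L || !is.numeric(seed) ||
      !is.finite(seed) || seed != round(seed)) {
    stop("seed must be a single integer")
  }
  invisible(TRUE)
}
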