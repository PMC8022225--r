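#' Cell geometry as stacked cylindrical segments
#'
#' A rod-shaped bacterial cell volume is represented by contiguous coaxial
#' cylindrical segments along the cell's long (x) axis: each segment spans
#' `[axial_start, axial_end)` microns and has a fixed radius. This mirrors
#' how segmented cell outlines are turned into 3D volumes for diffusion
#' simulations: the distance from the cell midline to the edge is used as
#' the radius of a cylinder for each length slice.
#'
#' @param axial_start,axial_end Segment boundaries along the long axis (µm).
#' @param radius Segment radii (µm), all positive.
#' @return An object of class `cell_geometry`: a data frame with columns
#'   `axial_start_um`, `axial_end_um`, `radius_um`.
#' @export
cell_geometry <- function(axial_start, axial_end, radius) {
  if (length(axial_start) != length(axial_end) ||
      length(axial_start) != length(radius)) {
    stop("segment vectors must have equal length")
  }
  if (length(radius) < 1L) stop("geometry needs at least one segment")
  if (any(!is.finite(axial_start)) || any(!is.finite(axial_end)) ||
      any(!is.finite(radius))) {
    stop("geometry fields must be finite")
  }
  if (any(radius <= 0)) stop("every segment radius must be > 0")
  if (any(axial_end <= axial_start)) stop("segments must have positive length")
  if (length(axial_start) > 1L &&
      any(abs(axial_start[-1L] - axial_end[-length(axial_end)]) > 1e-9)) {
    stop("segments must be contiguous and non-overlapping")
  }
  structure(
    data.frame(axial_start_um = as.numeric(axial_start),
               axial_end_um = as.numeric(axial_end),
               radius_um = as.numeric(radius)),
    class = c("cell_geometry", "data.frame"))
}

#' Canonical spherocylindrical cell volume
#'
#' Builds the standard rod-shaped cell: a cylinder of the given radius with
#' hemispherical end caps, discretized into `n_segments` equal axial slices.
#' Cap slices get radius `sqrt(radius^2 - a^2)` where `a` is the axial
#' distance of the slice midpoint from the cap's base plane, so the enclosed
#' volume converges to `pi r^2 (L - 2r) + 4/3 pi r^3` as slices are refined.
#'
#' @param length Total cell length pole-to-pole (µm); must exceed `2*radius`.
#' @param radius Cell radius (µm).
#' @param n_segments Number of axial slices (default 60).
#' @return A [cell_geometry()].
#' @examples
#' geom <- make_spherocylinder(3, 0.45)
#' geometry_volume(geom)
#' @export
make_spherocylinder <- function(length, radius, n_segments = 60L) {
  if (!is.numeric(length) || !is.numeric(radius) ||
      length <= 0 || radius <= 0) {
    stop("cell length and radius must be positive numbers")
  }
  if (length <= 2 * radius) {
    stop("cell length must exceed twice the radius (2*", radius, " um)")
  }
  n_segments <- as.integer(n_segments)
  if (n_segments < 3L) stop("need at least 3 segments")
  edges <- seq(0, length, length.out = n_segments + 1L)
  mid <- (edges[-1L] + edges[-(n_segments + 1L)]) / 2
  r <- rep(radius, n_segments)
  lo <- mid < radius                # left cap
  hi <- mid > length - radius       # right cap
  r[lo] <- sqrt(pmax(radius^2 - (radius - mid[lo])^2, 0))
  r[hi] <- sqrt(pmax(radius^2 - (mid[hi] - (length - radius))^2, 0))
  r <- pmax(r, 1e-6)                # slice midpoints never sit exactly at a pole
  cell_geometry(edges[-(n_segments + 1L)], edges[-1L], r)
}

#' Cell geometry from a segmented outline
#'
#' Converts a midline + half-width polyline (as produced by cell
#' segmentation tools) into a stack of cylindrical segments: one segment per
#' consecutive pair of outline points, with radius equal to the mean of the
#' two half-widths.
#'
#' @param midline_halfwidths Data frame or matrix with two columns: axial
#'   position (µm, strictly increasing) and half-width (µm, positive).
#' @return A [cell_geometry()].
#' @export
geometry_from_outline <- function(midline_halfwidths) {
  m <- as.matrix(midline_halfwidths)
  if (ncol(m) != 2L) stop("expected two columns: axial position, half-width")
  if (nrow(m) < 2L) stop("need at least 2 outline points")
  pos <- m[, 1L]; hw <- m[, 2L]
  if (any(diff(pos) <= 0)) stop("axial positions must be strictly increasing")
  if (any(hw <= 0)) stop("half-widths must be positive")
  n <- nrow(m)
  cell_geometry(pos[-n], pos[-1L], (hw[-n] + hw[-1L]) / 2)
}

#' Enclosed volume of a cell geometry
#'
#' @param geom A [cell_geometry()].
#' @return Volume in µm³.
#' @export
geometry_volume <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  sum(pi * geom$radius_um^2 * (geom$axial_end_um - geom$axial_start_um))
}

#' Total axial length of a cell geometry
#' @param geom A [cell_geometry()].
#' @return Length in µm.
#' @export
geometry_length <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  max(geom$axial_end_um) - min(geom$axial_start_um)
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("cell_geometry: %d segments, length %.3g um, max radius %.3g um\n",
              nrow(x), geometry_length(x), max(x$radius_um)))
  invisible(x)
}

#' Population of canonical cells for simulation-based inference
#'
#' Generates a set of spherocylindrical cell volumes standing in for
#' segmented cell outlines: fixed radius, lengths drawn uniformly over a
#' range. Used as the default geometry population when matching observed D*
#' distributions against simulations.
#'
#' @param n_cells Number of cells (default 50).
#' @param radius Cell radius (µm, default 0.45).
#' @param length_range Range of cell lengths (µm, default `c(2, 4)`).
#' @param n_segments Axial slices per cell.
#' @param seed Integer seed fixing the drawn lengths.
#' @return A list of [cell_geometry()] objects.
#' @export
default_cell_population <- function(n_cells = 50L, radius = 0.45,
                                    length_range = c(2, 4),
                                    n_segments = 60L, seed = 1L) {
  stopifnot(n_cells >= 1L, length(length_range) == 2L,
            length_range[1L] > 2 * radius)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  lens <- stats::runif(n_cells, length_range[1L], length_range[2L])
  lapply(lens, make_spherocylinder, radius = radius, n_segments = n_segments)
}

# Save/restore the global RNG state so helper draws do not perturb the
# caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
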