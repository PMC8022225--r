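# Shared fixtures: all synthetic, generated in code.

# Effectively unconfined volume: walls hundreds of diffusion lengths away.
big_cell <- function() make_spherocylinder(200, 50, 200)

# Idealized acquisition: single sub-frame (no motion blur), no
# localization noise, long movie so activation truncation is negligible.
ideal_acq <- function(frames = 1e5) {
  acquisition_model(n_subframes = 1L, sigma_loc = 0, movie_frames = frames)
}

# Verify ground-truth positions lie inside a cell geometry.
inside_geometry <- function(geom, x, y, z) {
  seg <- findInterval(x, c(geom$axial_start_um[1L], geom$axial_end_um),
                      rightmost.closed = TRUE)
  ok <- seg >= 1L & seg <= nrow(geom)
  r <- geom$radius_um[pmin(pmax(seg, 1L), nrow(geom))]
  ok & (y^2 + z^2 <= r^2 + 1e-9)
}

# Independent brute-force oracle for the linking assignment: enumerate
# every injective partial assignment of rows (track ends) to columns
# (localizations) with finite cost, and return the best (max cardinality,
# then min total distance). Exponential; for oracle-sized problems only.
brute_force_assignment <- function(dmat) {
  nr <- nrow(dmat); nc <- ncol(dmat)
  best <- list(count = -1L, total = Inf, asg = integer(nr))
  enumerate <- function(i, used, asg, count, total) {
    if (i > nr) {
      if (count > best$count ||
          (count == best$count && total < best$total)) {
        best <<- list(count = count, total = total, asg = asg)
      }
      return(invisible(NULL))
    }
    enumerate(i + 1L, used, asg, count, total)
    for (j in seq_len(nc)) {
      if (!used[j] && is.finite(dmat[i, j])) {
        used[j] <- TRUE; asg[i] <- j
        enumerate(i + 1L, used, asg, count + 1L, total + dmat[i, j])
        used[j] <- FALSE; asg[i] <- 0L
      }
    }
  }
  enumerate(1L, logical(nc), integer(nr), 0L, 0)
  best
}

# Stationary-emitter localization table: one row per emitter per frame.
stationary_locs <- function(pos, n_frames, cell_id = 1L) {
  do.call(rbind, lapply(seq_len(nrow(pos)), function(i) {
    data.frame(frame = 0:(n_frames - 1L), x_um = pos[i, 1L],
               y_um = pos[i, 2L], cell_id = cell_id)
  }))
}
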