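#' Link localizations into tracks
#'
#' Links single-molecule localizations across frames: positions appearing
#' in consecutive frames within `max_disp` of an active track end are
#' linked; when several localizations compete for several track ends, the
#' one-to-one assignment minimizing the summed step distance is chosen
#' (solved exactly per frame pair). A track whose molecule disappears for
#' up to `memory` frames (blinking or a missed localization) may be
#' resumed within the same window; no position is interpolated for the
#' missing frame. Unassigned localizations start new tracks.
#'
#' Linking is performed independently within each `cell_id`. Ties are
#' broken deterministically by (frame, x, y) order.
#'
#' @param locs Localization table: data frame with columns `frame`,
#'   `x_um`, `y_um`, optionally `cell_id`.
#' @param max_disp Search window per linking step (µm, default 0.48, i.e.
#'   5 pixels of 96 nm). Memory links use the same window.
#' @param memory Number of missed frames a track may survive (default 1).
#' @return Data frame `track_id`, `frame`, `x_um`, `y_um`, `cell_id`,
#'   sorted by track then frame.
#' @export
link_tracks <- function(locs, max_disp = 0.48, memory = 1L) {
  stopifnot(max_disp > 0, memory >= 0)
  if (nrow(locs) == 0L) {
    return(data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      cell_id = integer()))
  }
  if (!"cell_id" %in% names(locs)) locs$cell_id <- 1L
  memory <- as.integer(memory)
  pieces <- lapply(split(locs, locs$cell_id), link_one_cell,
                   max_disp = max_disp, memory = memory)
  offset <- 0L
  for (i in seq_along(pieces)) {
    if (nrow(pieces[[i]]) == 0L) next
    m <- max(pieces[[i]]$track_id)
    pieces[[i]]$track_id <- pieces[[i]]$track_id + offset
    offset <- offset + m
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$track_id, out$frame), ]
}

link_one_cell <- function(locs, max_disp, memory) {
  o <- order(locs$frame, locs$x_um, locs$y_um)
  locs <- locs[o, ]
  n <- nrow(locs)
  track_of <- integer(n)
  # active track ends: row index of last localization per track
  last_row <- integer(0)   # indexed by track id
  last_frame <- integer(0)
  next_id <- 1L
  frames <- sort(unique(locs$frame))
  rows_by_frame <- split(seq_len(n), locs$frame)
  for (f in frames) {
    rows <- rows_by_frame[[as.character(f)]]
    unmatched <- rows
    # linking stages: gap 1 (consecutive frames) first, then memory gaps
    for (gap in seq_len(memory + 1L)) {
      if (length(unmatched) == 0L) break
      cand_tracks <- which(last_frame == f - gap)
      if (length(cand_tracks) == 0L) next
      px <- locs$x_um[last_row[cand_tracks]]
      py <- locs$y_um[last_row[cand_tracks]]
      qx <- locs$x_um[unmatched]; qy <- locs$y_um[unmatched]
      dmat <- sqrt(outer(px, qx, "-")^2 + outer(py, qy, "-")^2)
      dmat[dmat > max_disp] <- Inf
      asg <- min_distance_assignment(dmat)
      for (k in seq_along(asg)) {
        if (asg[k] > 0L) {
          tid <- cand_tracks[k]
          row <- unmatched[asg[k]]
          track_of[row] <- tid
          last_row[tid] <- row
          last_frame[tid] <- f
        }
      }
      unmatched <- unmatched[!unmatched %in%
                               last_row[cand_tracks[asg > 0L]]]
    }
    for (row in unmatched) {
      track_of[row] <- next_id
      last_row[next_id] <- row
      last_frame[next_id] <- f
      next_id <- next_id + 1L
    }
  }
  data.frame(track_id = track_of, frame = locs$frame,
             x_um = locs$x_um, y_um = locs$y_um, cell_id = locs$cell_id)
}

# Exact minimum-total-distance assignment among candidate pairs.
# dmat[i, j]: distance from track end i to localization j, Inf if outside
# the search window. Maximum cardinality takes priority over total
# distance (standard particle-linking objective). Conflicts decompose into
# small connected components under sparse activation; each component is
# solved by depth-first search with pruning. Returns, per track end, the
# assigned localization column (0 = none).
min_distance_assignment <- function(dmat) {
  nr <- nrow(dmat); nc <- ncol(dmat)
  asg <- integer(nr)
  if (nr == 0L || nc == 0L) return(asg)
  finite <- is.finite(dmat)
  if (!any(finite)) return(asg)
  # connected components of the bipartite candidate graph
  comp_row <- integer(nr); comp_col <- integer(nc); ncomp <- 0L
  for (i in seq_len(nr)) {
    if (comp_row[i] == 0L && any(finite[i, ])) {
      ncomp <- ncomp + 1L
      stack_r <- i
      while (length(stack_r) > 0L) {
        r <- stack_r[1L]; stack_r <- stack_r[-1L]
        if (comp_row[r] != 0L) next
        comp_row[r] <- ncomp
        cols <- which(finite[r, ] & comp_col == 0L)
        comp_col[cols] <- ncomp
        for (cc in cols) {
          stack_r <- c(stack_r, which(finite[, cc] & comp_row == 0L))
        }
      }
    }
  }
  for (k in seq_len(ncomp)) {
    ri <- which(comp_row == k); ci <- which(comp_col == k)
    sub <- matrix(dmat[ri, ci], nrow = length(ri))
    best <- assign_component(sub)
    hit <- best > 0L
    asg[ri[hit]] <- ci[best[hit]]
  }
  asg
}

# Depth-first branch-and-bound over one conflict component: maximize the
# number of links, then minimize their summed distance.
assign_component <- function(d) {
  nr <- nrow(d); nc <- ncol(d)
  best_cnt <- -1L; best_sum <- Inf; best_asg <- integer(nr)
  used <- logical(nc)
  asg <- integer(nr)
  recurse <- function(i, cnt, tot) {
    if (i > nr) {
      if (cnt > best_cnt || (cnt == best_cnt && tot < best_sum)) {
        best_cnt <<- cnt; best_sum <<- tot; best_asg <<- asg
      }
      return(invisible(NULL))
    }
    remaining <- nr - i + 1L
    if (cnt + remaining < best_cnt) return(invisible(NULL))
    cols <- which(is.finite(d[i, ]) & !used)
    for (j in cols[order(d[i, cols])]) {
      used[j] <<- TRUE; asg[i] <<- j
      recurse(i + 1L, cnt + 1L, tot + d[i, j])
      used[j] <<- FALSE; asg[i] <<- 0L
    }
    recurse(i + 1L, cnt, tot)  # leave track end i unlinked
  }
  recurse(1L, 0L, 0)
  best_asg
}
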