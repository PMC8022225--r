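#' Read and write the tabular interchange formats
#'
#' Localization tables (`frame,x_um,y_um,cell_id[,track_id]`), track
#' tables (`track_id,frame,x_um,y_um,cell_id`) and cell geometries
#' (`axial_start_um,axial_end_um,radius_um`) are plain CSV files with a
#' header, values in µm and 0-based frame indices.
#'
#' @param x Object to write (data frame or `cell_geometry`).
#' @param path File path.
#' @return Readers return a data frame (`read_geometry` a
#'   [cell_geometry()]); writers return `path` invisibly.
#' @export
write_localizations <- function(x, path) {
  need <- c("frame", "x_um", "y_um", "cell_id")
  stopifnot(all(need %in% names(x)))
  cols <- c(need, intersect("track_id", names(x)))
  utils::write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_localizations
#' @export
write_tracks <- function(x, path) {
  need <- c("track_id", "frame", "x_um", "y_um", "cell_id")
  stopifnot(all(need %in% names(x)))
  utils::write.csv(x[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_tracks <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_localizations
#' @export
write_geometry <- function(x, path) {
  stopifnot(inherits(x, "cell_geometry"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_geometry <- function(path) {
  d <- utils::read.csv(path)
  cell_geometry(d$axial_start_um, d$axial_end_um, d$radius_um)
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration mirroring the [motion_model()] and
#' [acquisition_model()] field names, plus pipeline stage settings; see
#' [run_pipeline()].
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
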