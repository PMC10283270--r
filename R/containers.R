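#' Acquisition metadata for a Z-movie series
#'
#' Bundles the geometry and timing of the light-sheet acquisition. The
#' exposure time per frame (`exposure_ms`) is the `E` entering the
#' cycle-length formula `L = N/3 * E`; by default it is derived from the
#' frame rate (`1000 / frame_rate`).
#'
#' @param frame_rate Acquisition rate in frames per second (> 0).
#' @param exposure_ms Exposure/interval per frame in milliseconds. Defaults
#'   to `1000 / frame_rate`.
#' @param pixel_size_xy Lateral pixel size in micrometres (> 0).
#' @param step_size_z Axial step between consecutive Z-movies in
#'   micrometres (> 0).
#' @param bit_depth Stored intensity bit depth (8 or 16).
#' @return An object of class `acquisition_meta`.
#' @examples
#' acquisition_meta(frame_rate = 200)
#' @export
acquisition_meta <- function(frame_rate = 200,
                             exposure_ms = 1000 / frame_rate,
                             pixel_size_xy = 0.325,
                             step_size_z = 1,
                             bit_depth = 16L) {
  stopifnot(is.numeric(frame_rate), length(frame_rate) == 1L, frame_rate > 0,
            is.numeric(exposure_ms), exposure_ms > 0,
            pixel_size_xy > 0, step_size_z > 0,
            bit_depth %in% c(8L, 16L))
  structure(list(frame_rate = frame_rate,
                 exposure_ms = exposure_ms,
                 pixel_size_xy = pixel_size_xy,
                 step_size_z = step_size_z,
                 bit_depth = as.integer(bit_depth)),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("Acquisition: %.6g fps (E = %.6g ms), pixel %.4g um, z-step %.4g um, %d-bit\n",
              x$frame_rate, x$exposure_ms, x$pixel_size_xy, x$step_size_z, x$bit_depth))
  invisible(x)
}

#' Construct a Z-movie
#'
#' A Z-movie is the time-lapse recorded at one fixed depth while the heart
#' beats: an ordered stack of equally shaped 2D frames plus its
#' acquisition metadata. Frames are stored as a numeric `height x width x
#' n_frames` array; intensities must be non-negative. Indices are 0-based
#' in all public interfaces (`z_index`, frame/time indices).
#'
#' @param frames Numeric array `h x w x t` (t >= 2) or list of matrices.
#' @param z_index 0-based axial slice index.
#' @param meta An [acquisition_meta()] object.
#' @return An object of class `zmovie`.
#' @export
zmovie <- function(frames, z_index = 0L, meta = acquisition_meta()) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("mixed frame shapes in Z-movie")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be an h x w x t array")
  if (dim(frames)[3] < 2L) stop("too few frames: a Z-movie needs at least 2")
  if (min(frames) < 0) stop("intensities must be non-negative")
  stopifnot(inherits(meta, "acquisition_meta"))
  structure(list(z_index = as.integer(z_index),
                 frames = frames,
                 meta = meta),
            class = "zmovie")
}

n_frames <- function(movie) dim(movie$frames)[3]

#' @export
print.zmovie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Z-movie z=%d: %d frames of %d x %d (%.4g um/px)\n",
              x$z_index, d[3], d[1], d[2], x$meta$pixel_size_xy))
  invisible(x)
}

#' Construct a Z-stack series
#'
#' The full acquisition: one Z-movie per depth, ordered by `z_index`
#' (contiguous from 0), sharing frame shape and metadata.
#'
#' @param movies List of [zmovie()] objects.
#' @param meta Shared [acquisition_meta()]; defaults to the first movie's.
#' @return An object of class `zstack_series`.
#' @export
zstack_series <- function(movies, meta = movies[[1]]$meta) {
  stopifnot(length(movies) >= 1L, all(vapply(movies, inherits, TRUE, "zmovie")))
  z <- vapply(movies, `[[`, 0L, "z_index")
  if (!identical(as.integer(z), seq_along(movies) - 1L))
    stop("z_index must be contiguous from 0 and strictly increasing")
  shp <- unique(lapply(movies, function(m) dim(m$frames)[1:2]))
  if (length(shp) != 1L) stop("all movies must share frame shape")
  structure(list(movies = movies, meta = meta), class = "zstack_series")
}

#' @export
print.zstack_series <- function(x, ...) {
  d <- dim(x$movies[[1]]$frames)
  cat(sprintf("Z-stack series: %d slices, %d x %d x %d frames each\n",
              length(x$movies), d[1], d[2], d[3]))
  print(x$meta)
  invisible(x)
}

#' Construct a 4D (3D + time) reconstruction
#'
#' @param volumes List of 3D numeric arrays (`h x w x nz`), one per
#'   timepoint, all the same shape.
#' @param time_step Time between volumes in milliseconds (the exposure of
#'   the source series).
#' @param voxel_size Numeric length-3 `(x, y, z)` voxel size in micrometres.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(volumes, time_step, voxel_size) {
  stopifnot(is.list(volumes), length(volumes) >= 1L,
            is.numeric(time_step), time_step > 0,
            is.numeric(voxel_size), length(voxel_size) == 3L, all(voxel_size > 0))
  shp <- unique(lapply(volumes, dim))
  if (length(shp) != 1L || length(shp[[1]]) != 3L)
    stop("all volumes must be 3D arrays of identical shape")
  structure(list(volumes = volumes,
                 time_step = time_step,
                 voxel_size = as.numeric(voxel_size)),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat(sprintf("4D reconstruction: %d timepoints (dt = %.4g ms), volume %d x %d x %d, voxel (%.4g, %.4g, %.4g) um\n",
              length(x$volumes), x$time_step, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}
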