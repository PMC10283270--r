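## On-disk conventions: one multi-page grayscale TIFF per Z-movie named
## z####.tif (4-digit, 0-based), one multi-page TIFF per reconstruction
## timepoint named t####.tif with pages = z slices, plus a JSON manifest.
## Stored intensities are unsigned integers; all in-memory math is double.

.int_max <- function(bit_depth) 2^bit_depth - 1

.read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- unique(lapply(pages, dim))
  if (length(shp) != 1L) stop("mixed page shapes in ", path)
  pages
}

.write_pages <- function(pages, path, bit_depth) {
  mx <- .int_max(bit_depth)
  bad <- vapply(pages, function(p) any(p < 0 | p > mx | p != round(p)), TRUE)
  if (any(bad))
    stop(sprintf("intensities must be integers in [0, %d] for %d-bit storage",
                 mx, bit_depth))
  tiff::writeTIFF(lapply(pages, function(p) p / mx), path,
                  bits.per.sample = as.integer(bit_depth),
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read a Z-movie from a multi-page TIFF
#'
#' @param path Multi-page grayscale TIFF with at least 2 pages.
#' @param meta [acquisition_meta()] for the acquisition.
#' @param z_index 0-based slice index; if `NULL`, parsed from a
#'   `z####.tif` filename.
#' @return A [zmovie()].
#' @seealso [write_zmovie()], [read_zstack_series()]
#' @export
read_zmovie <- function(path, meta = acquisition_meta(), z_index = NULL) {
  if (!file.exists(path)) stop("cannot read ", path)
  pages <- .read_pages(path)
  if (length(pages) < 2L)
    stop("too few frames: ", path, " has ", length(pages), " page(s)")
  if (is.null(z_index)) {
    m <- regmatches(basename(path), regexec("z(\\d{4})\\.tif{1,2}$", basename(path)))[[1]]
    if (length(m) < 2L)
      stop("z_index not supplied and filename does not match z####.tif: ", basename(path))
    z_index <- as.integer(m[2])
  }
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(dim(pages[[1]]), length(pages)))
  storage.mode(frames) <- "double"
  zmovie(frames, z_index, meta)
}

#' Write a Z-movie to a multi-page TIFF
#'
#' @param movie A [zmovie()]; intensities must be integers within the
#'   metadata bit depth.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_zmovie <- function(movie, path) {
  stopifnot(inherits(movie, "zmovie"))
  pages <- lapply(seq_len(n_frames(movie)), function(t) movie$frames[, , t])
  .write_pages(pages, path, movie$meta$bit_depth)
}

#' Write a Z-stack series as z####.tif files
#'
#' @param series A [zstack_series()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_zstack_series <- function(series, dir) {
  stopifnot(inherits(series, "zstack_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in series$movies)
    write_zmovie(m, file.path(dir, sprintf("z%04d.tif", m$z_index)))
  invisible(dir)
}

#' Read a Z-stack series from a directory of z####.tif files
#'
#' @param dir Directory containing `z####.tif` movies.
#' @param meta Shared [acquisition_meta()].
#' @return A [zstack_series()].
#' @export
read_zstack_series <- function(dir, meta = acquisition_meta()) {
  paths <- sort(list.files(dir, pattern = "^z\\d{4}\\.tif{1,2}$", full.names = TRUE))
  if (!length(paths)) stop("no z####.tif files in ", dir)
  zstack_series(lapply(paths, read_zmovie, meta = meta), meta = meta)
}

#' Write a 4D reconstruction to disk
#'
#' Writes one multi-page TIFF per timepoint (`t####.tif`, pages in z
#' order) and a `manifest.json` recording the time step, voxel size and
#' bit depth so that [read_volume4d()] reconstructs an equal object.
#'
#' @param v A [volume4d()] with integer intensities.
#' @param dir Output directory.
#' @param bit_depth Stored bit depth (default 16).
#' @return The manifest file path, invisibly.
#' @export
write_volume4d <- function(v, dir, bit_depth = 16L) {
  stopifnot(inherits(v, "volume4d"))
  if (!length(v$volumes)) stop("empty Volume4D")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(v$volumes)) {
    vol <- v$volumes[[t]]
    pages <- lapply(seq_len(dim(vol)[3]), function(z) vol[, , z])
    .write_pages(pages, file.path(dir, sprintf("t%04d.tif", t - 1L)), bit_depth)
  }
  manifest <- list(format = "beatsync-volume4d",
                   index_base = 0L,
                   n_timepoints = length(v$volumes),
                   shape = dim(v$volumes[[1]]),
                   time_step_ms = v$time_step,
                   voxel_size_um = v$voxel_size,
                   bit_depth = as.integer(bit_depth))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

#' Read a 4D reconstruction written by [write_volume4d()]
#'
#' @param dir Directory containing `t####.tif` files and `manifest.json`.
#' @return A [volume4d()].
#' @export
read_volume4d <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  vols <- lapply(seq_len(man$n_timepoints) - 1L, function(t) {
    pages <- .read_pages(file.path(dir, sprintf("t%04d.tif", t)))
    a <- array(unlist(pages, use.names = FALSE), dim = c(dim(pages[[1]]), length(pages)))
    storage.mode(a) <- "double"
    a
  })
  volume4d(vols, time_step = as.numeric(man$time_step_ms),
           voxel_size = as.numeric(man$voxel_size_um))
}
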