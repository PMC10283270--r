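#' Construct a single cell track
#'
#' A track is one nucleus followed through the reconstruction: centroid
#' per timepoint (micrometres; `NA` rows flag gaps where the nucleus was
#' not found), voxel count, morphology and a region annotation. Tracks
#' are defined on the full time axis of their source volumes.
#'
#' @param cell_id Integer track identifier (stable within a tracking run).
#' @param centroid `T x 3` numeric matrix of `(x, y, z)` centroids in um.
#' @param time_ms Numeric vector of length `T`.
#' @param n_voxels,volume_um3,surface_um2 Per-timepoint measurements
#'   (defaults `NA`).
#' @param region One of `"ventricle"`, `"atrium"`, `"AVC"`, `"unassigned"`.
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(cell_id, centroid, time_ms,
                       n_voxels = rep(NA_real_, nrow(centroid)),
                       volume_um3 = rep(NA_real_, nrow(centroid)),
                       surface_um2 = rep(NA_real_, nrow(centroid)),
                       region = "unassigned") {
  centroid <- as.matrix(centroid)
  stopifnot(ncol(centroid) == 3L, length(time_ms) == nrow(centroid),
            region %in% c("ventricle", "atrium", "AVC", "unassigned"))
  colnames(centroid) <- c("x", "y", "z")
  structure(list(cell_id = as.integer(cell_id),
                 centroid = centroid,
                 time_ms = as.numeric(time_ms),
                 n_voxels = n_voxels,
                 volume_um3 = volume_um3,
                 surface_um2 = surface_um2,
                 region = region,
                 gap = !stats::complete.cases(centroid)),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("Cell track %d (%s): %d timepoints, %d gap(s)\n",
              x$cell_id, x$region, nrow(x$centroid), sum(x$gap)))
  invisible(x)
}

#' Write cell tracks to a long-format CSV
#'
#' One row per (cell, timepoint) with columns `cell_id`, `t_index`
#' (0-based), `time_ms`, `x_um`, `y_um`, `z_um`, `region`, `volume_um3`,
#' `surface_um2`, ordered by `cell_id` then `t_index`. All tracks must
#' share one time axis.
#'
#' @param tracks List of [cell_track()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, TRUE, "cell_track")))
  axes <- unique(lapply(tracks, `[[`, "time_ms"))
  if (length(axes) != 1L) stop("ragged time axes: all tracks must share one time axis")
  tab <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(cell_id = tr$cell_id,
               t_index = seq_along(tr$time_ms) - 1L,
               time_ms = tr$time_ms,
               x_um = tr$centroid[, "x"],
               y_um = tr$centroid[, "y"],
               z_um = tr$centroid[, "z"],
               region = tr$region,
               volume_um3 = tr$volume_um3,
               surface_um2 = tr$surface_um2)
  }))
  tab <- tab[order(tab$cell_id, tab$t_index), ]
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read cell tracks written by [write_tracks()]
#'
#' @param path CSV path.
#' @return List of [cell_track()] objects.
#' @export
read_tracks <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[order(tab$cell_id, tab$t_index), ]
  unname(lapply(split(tab, factor(tab$cell_id, levels = unique(tab$cell_id))), function(d) {
    d <- d[order(d$t_index), ]
    cell_track(cell_id = d$cell_id[1],
               centroid = cbind(d$x_um, d$y_um, d$z_um),
               time_ms = d$time_ms,
               volume_um3 = d$volume_um3,
               surface_um2 = d$surface_um2,
               region = d$region[1])
  }))
}
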