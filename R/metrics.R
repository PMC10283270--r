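## Single-cell contractility metrics: displacement, speed, pairwise
## distance, surface/volume morphology, regional summaries, mesh export.

#' Displacement of a cell from its starting position
#'
#' `d(t) = ||c(t) - c(0)||` in micrometres; gaps propagate as `NA`.
#'
#' @param track A [cell_track()] with no gap at `t = 0`.
#' @return Numeric vector over the track's time axis (`d[1] == 0`).
#' @export
displacement_series <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  if (track$gap[1]) stop("gap at t = 0: displacement reference undefined")
  sqrt(rowSums((track$centroid -
                  matrix(track$centroid[1, ], nrow(track$centroid), 3,
                         byrow = TRUE))^2))
}

#' Speed of a cell along its track
#'
#' Central differences on interior points, one-sided at the ends:
#' `v(t) = ||c(t+1) - c(t-1)|| / (2 dt)`. Gaps propagate as `NA` in any
#' estimate touching them. The average velocity is the mean over defined
#' points.
#'
#' @param track A [cell_track()] with >= 3 timepoints.
#' @param dt_ms Sampling interval (ms); defaults to the track time axis.
#' @param method `"central"` (default) or `"forward"` differences.
#' @return List with `speed` (um/ms per timepoint) and
#'   `average_velocity`.
#' @export
velocity_series <- function(track, dt_ms = diff(track$time_ms[1:2]),
                            method = c("central", "forward")) {
  stopifnot(inherits(track, "cell_track"))
  method <- match.arg(method)
  C <- track$centroid
  T_n <- nrow(C)
  if (T_n < 3L) stop("need at least 3 timepoints")
  if (all(track$gap)) stop("all-gap track")
  v <- rep(NA_real_, T_n)
  if (method == "central") {
    i <- 2:(T_n - 1)
    v[i] <- sqrt(rowSums((C[i + 1, , drop = FALSE] - C[i - 1, , drop = FALSE])^2)) / (2 * dt_ms)
    v[1] <- sqrt(sum((C[2, ] - C[1, ])^2)) / dt_ms
    v[T_n] <- sqrt(sum((C[T_n, ] - C[T_n - 1, ])^2)) / dt_ms
  } else {
    i <- 1:(T_n - 1)
    v[i] <- sqrt(rowSums((C[i + 1, , drop = FALSE] - C[i, , drop = FALSE])^2)) / dt_ms
    v[T_n] <- v[T_n - 1]
  }
  list(speed = v, average_velocity = mean(v, na.rm = TRUE))
}

#' Pairwise distance between two tracked cells over time
#'
#' @param track_a,track_b [cell_track()] objects on a common time axis.
#' @return Object of class `pair_distance`: `cell_id_a`, `cell_id_b`,
#'   `distance_um` per timepoint (`NA` where either track has a gap).
#' @export
pair_distance <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "cell_track"), inherits(track_b, "cell_track"))
  if (!isTRUE(all.equal(track_a$time_ms, track_b$time_ms)))
    stop("disjoint time axes")
  structure(list(cell_id_a = track_a$cell_id, cell_id_b = track_b$cell_id,
                 time_ms = track_a$time_ms,
                 distance_um = sqrt(rowSums((track_a$centroid - track_b$centroid)^2))),
            class = "pair_distance")
}

#' Surface area and volume of one segmented cell
#'
#' Volume is the voxel count times the voxel volume; surface area is the
#' area of the triangulated 0.5-level iso-surface of the cell's binary
#' mask ([mask_mesh()]) with physical voxel scaling.
#'
#' @param label_volume A [segment_nuclei()] result.
#' @param cell_id Label present in the volume.
#' @param voxel_size Defaults to the label volume's.
#' @param smooth_sigma Mask pre-smoothing in voxels (see [mask_mesh()]).
#' @return List with `surface_um2`, `volume_um3`, `sav_ratio` (1/um).
#' @export
cell_surface_volume <- function(label_volume, cell_id,
                                voxel_size = label_volume$voxel_size,
                                smooth_sigma = 0.6) {
  stopifnot(inherits(label_volume, "label_volume"))
  idx <- which(label_volume$labels == cell_id)
  if (!length(idx)) stop("cell_id ", cell_id, " absent from label volume")
  d <- dim(label_volume$labels)
  ai <- arrayInd(idx, d)
  pad <- max(4L, ceiling(3 * smooth_sigma) + 1L)
  r1 <- max(1, min(ai[, 1]) - pad):min(d[1], max(ai[, 1]) + pad)
  r2 <- max(1, min(ai[, 2]) - pad):min(d[2], max(ai[, 2]) + pad)
  r3 <- max(1, min(ai[, 3]) - pad):min(d[3], max(ai[, 3]) + pad)
  sub <- label_volume$labels[r1, r2, r3, drop = FALSE] == cell_id
  mesh <- mask_mesh(sub, voxel_size = voxel_size, smooth_sigma = smooth_sigma)
  vol <- length(idx) * prod(voxel_size)
  area <- mesh_area(mesh)
  list(surface_um2 = area, volume_um3 = vol, sav_ratio = area / vol)
}

#' Attach morphology measurements to tracks
#'
#' Fills each track's per-timepoint `volume_um3` and `surface_um2` from
#' the label volumes it was linked over.
#'
#' @param tracks Output of [link_tracks()].
#' @param label_volumes The same list the tracks were linked from.
#' @param smooth_sigma Passed to [cell_surface_volume()].
#' @return The tracks, with morphology filled in.
#' @export
track_morphology <- function(tracks, label_volumes, smooth_sigma = 0.6) {
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    for (t in seq_along(tr$time_ms)) {
      lab <- tr$label_per_t[t]
      if (is.na(lab)) next
      sv <- cell_surface_volume(label_volumes[[t]], lab, smooth_sigma = smooth_sigma)
      tr$surface_um2[t] <- sv$surface_um2
      tr$volume_um3[t] <- sv$volume_um3
    }
    tracks[[i]] <- tr
  }
  tracks
}

#' Per-region summary of contractility metrics
#'
#' Mean and standard deviation of average velocity, SA:V ratio and
#' maximum displacement per anatomical region. Requested regions with no
#' tracks are reported as empty rows, never dropped.
#'
#' @param tracks List of [cell_track()] objects (with regions assigned;
#'   morphology optional).
#' @param dt_ms Sampling interval (ms).
#' @param regions Regions to report.
#' @return data.frame with one row per region.
#' @export
region_summary <- function(tracks, dt_ms = diff(tracks[[1]]$time_ms[1:2]),
                           regions = c("ventricle", "atrium", "AVC")) {
  per_track <- do.call(rbind, lapply(tracks, function(tr) {
    av <- tryCatch(velocity_series(tr, dt_ms)$average_velocity,
                   error = function(e) NA_real_)
    dmax <- tryCatch(max(displacement_series(tr), na.rm = TRUE),
                     error = function(e) NA_real_)
    sav <- if (all(is.na(tr$surface_um2))) NA_real_ else
      mean(tr$surface_um2 / tr$volume_um3, na.rm = TRUE)
    data.frame(region = tr$region, avg_velocity = av, max_displacement = dmax,
               sav_ratio = sav)
  }))
  do.call(rbind, lapply(regions, function(rg) {
    d <- per_track[per_track$region == rg, , drop = FALSE]
    data.frame(region = rg, n = nrow(d),
               avg_velocity_mean = if (nrow(d)) mean(d$avg_velocity, na.rm = TRUE) else NA_real_,
               avg_velocity_sd = if (nrow(d) > 1) sd(d$avg_velocity) else NA_real_,
               max_displacement_mean = if (nrow(d)) mean(d$max_displacement, na.rm = TRUE) else NA_real_,
               sav_ratio_mean = if (nrow(d)) mean(d$sav_ratio, na.rm = TRUE) else NA_real_)
  }))
}

#' Export one surface mesh per segmented cell
#'
#' Writes a Wavefront OBJ per label (physical coordinates) with a unique
#' colour per cell in the companion material file.
#'
#' @param label_volume A [segment_nuclei()] result with >= 1 label.
#' @param out_dir Output directory.
#' @param voxel_size Defaults to the label volume's.
#' @param smooth_sigma Passed to [mask_mesh()].
#' @return Character vector of written OBJ paths, invisibly.
#' @export
export_cell_meshes <- function(label_volume, out_dir,
                               voxel_size = label_volume$voxel_size,
                               smooth_sigma = 0.6) {
  stopifnot(inherits(label_volume, "label_volume"))
  ids <- label_volume$table$label
  if (!length(ids)) stop("no labels to export")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(label_volume$labels)
  paths <- character(length(ids))
  for (k in seq_along(ids)) {
    idx <- which(label_volume$labels == ids[k])
    ai <- arrayInd(idx, d)
    pad <- max(4L, ceiling(3 * smooth_sigma) + 1L)
    r1 <- max(1, min(ai[, 1]) - pad):min(d[1], max(ai[, 1]) + pad)
    r2 <- max(1, min(ai[, 2]) - pad):min(d[2], max(ai[, 2]) + pad)
    r3 <- max(1, min(ai[, 3]) - pad):min(d[3], max(ai[, 3]) + pad)
    sub <- label_volume$labels[r1, r2, r3, drop = FALSE] == ids[k]
    mesh <- mask_mesh(sub, voxel_size = voxel_size, smooth_sigma = smooth_sigma)
    ## shift mesh back to whole-volume physical coordinates
    mesh$vertices[, "x"] <- mesh$vertices[, "x"] + (r2[1] - 1) * voxel_size[1]
    mesh$vertices[, "y"] <- mesh$vertices[, "y"] + (r1[1] - 1) * voxel_size[2]
    mesh$vertices[, "z"] <- mesh$vertices[, "z"] + (r3[1] - 1) * voxel_size[3]
    col <- hsv((k - 1) / max(1, length(ids)), 0.7, 0.9)
    rgb <- grDevices::col2rgb(col)[, 1] / 255
    paths[k] <- file.path(out_dir, sprintf("cell%04d.obj", ids[k]))
    write_obj(mesh, paths[k], color = rgb, name = sprintf("cell%04d", ids[k]))
  }
  invisible(paths)
}

#' Re-anchor a time axis so phase zero is end-systole
#'
#' Finds the timepoint of minimal ventricular-mask volume (end-systole)
#' in a sequence of label volumes restricted to a ventricle mask and
#' returns the circular re-indexing that makes it timepoint 0.
#'
#' @param label_volumes Time-ordered [segment_nuclei()] results.
#' @param ventricle_mask Logical/integer array selecting the ventricle.
#' @return Integer vector `ord` such that `x[ord]` starts at end-systole.
#' @export
anchor_end_systole <- function(label_volumes, ventricle_mask) {
  vols <- vapply(label_volumes, function(lv)
    sum(lv$labels > 0L & ventricle_mask > 0), 0)
  k <- which.min(vols)
  c(k:length(vols), seq_len(k - 1L))
}
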