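## Nuclei segmentation and tracking: a classical threshold + seeded
## watershed + greedy nearest-neighbour pipeline with a tracker-agnostic
## interface (label volumes in, cell tracks out).

.otsu3d <- function(v, levels = 256L) {
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(levels, floor((v - r[1]) / diff(r) * levels) + 1L), levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  r[1] + k / levels * diff(r)
}

## strict-ish local maxima of a 3D array above a floor, 26-neighbourhood
.local_maxima3 <- function(v, floor_val) {
  d <- dim(v)
  cand <- which(v > floor_val)
  if (!length(cand)) return(integer(0))
  ai <- arrayInd(cand, d)
  interior <- ai[, 1] > 1 & ai[, 1] < d[1] & ai[, 2] > 1 & ai[, 2] < d[2] &
    ai[, 3] > 1 & ai[, 3] < d[3]
  cand <- cand[interior]
  if (!length(cand)) return(integer(0))
  offs <- as.vector(outer(outer(-1:1, (-1:1) * d[1], "+"), (-1:1) * d[1] * d[2], "+"))
  offs <- offs[offs != 0]
  keep <- rep(TRUE, length(cand))
  v0 <- v[cand]
  for (o in offs) keep <- keep & v0 >= v[cand + o]
  cand[keep]
}

#' Segment nuclei in a 3D volume by seeded watershed
#'
#' Foreground is selected by a global threshold (Otsu or fixed); seeds
#' are local maxima of the foreground distance transform separated by at
#' least `min_seed_separation_um`; labels are grown from the seeds over
#' the foreground (watershed-style region splitting of touching nuclei).
#' Components smaller than `min_voxels` are removed and labels renumbered
#' consecutively in scan order.
#'
#' @param volume 3D numeric array `[y, x, z]`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value Intensity cutoff when `threshold_method =
#'   "fixed"`.
#' @param min_voxels Minimum component size (default 5).
#' @param min_seed_separation_um Minimum seed distance (um).
#' @param voxel_size `(x, y, z)` voxel size (um).
#' @return Object of class `label_volume`: integer `labels` array
#'   (0 = background), `voxel_size`, and a `table` data.frame with
#'   per-label voxel counts and centroids in um.
#' @export
segment_nuclei <- function(volume, threshold_method = c("otsu", "fixed"),
                           threshold_value = NULL, min_voxels = 5L,
                           min_seed_separation_um = 2,
                           voxel_size = c(1, 1, 1)) {
  threshold_method <- match.arg(threshold_method)
  d <- dim(volume)
  stopifnot(length(d) == 3L)
  thr <- if (threshold_method == "fixed") {
    if (is.null(threshold_value)) stop("threshold_value required for fixed thresholding")
    threshold_value
  } else .otsu3d(volume)
  bin <- volume > thr
  empty <- structure(list(labels = array(0L, d), voxel_size = voxel_size,
                          table = data.frame(label = integer(0), n_voxels = integer(0),
                                             x_um = numeric(0), y_um = numeric(0),
                                             z_um = numeric(0))),
                     class = "label_volume")
  if (!any(bin)) return(empty)
  dmap <- EBImage::distmap(array(as.numeric(bin), d))
  peaks <- .local_maxima3(dmap, 0)
  if (!length(peaks)) peaks <- which.max(dmap)
  ai <- arrayInd(peaks, d)
  pos_um <- cbind((ai[, 2] - 1) * voxel_size[1], (ai[, 1] - 1) * voxel_size[2],
                  (ai[, 3] - 1) * voxel_size[3])
  ord <- order(dmap[peaks], volume[peaks], decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        min(sqrt(colSums((t(pos_um[keep, , drop = FALSE]) - pos_um[i, ])^2))) >= min_seed_separation_um)
      keep <- c(keep, i)
  }
  keep <- keep[order(peaks[keep])]
  seeds <- array(0L, d)
  seeds[peaks[keep]] <- seq_along(keep)
  lab <- EBImage::propagate(volume, seeds, mask = bin)
  lab <- array(as.integer(round(lab)), d)
  ## size filter + consecutive renumbering in scan order
  counts <- tabulate(lab[lab > 0L])
  ok <- which(counts >= min_voxels)
  if (!length(ok)) return(empty)
  first_idx <- vapply(ok, function(l) which.max(lab == l), 0L)
  ok <- ok[order(first_idx)]
  remap <- integer(length(counts))
  remap[ok] <- seq_along(ok)
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  ## intensity-weighted centroids: binary centroids are sensitive to how
  ## the watershed boundary splits touching nuclei
  tab <- do.call(rbind, lapply(seq_along(ok), function(new) {
    idx <- which(lab == new)
    a <- arrayInd(idx, d)
    w <- volume[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    data.frame(label = new, n_voxels = length(idx),
               x_um = sum((a[, 2] - 1) * w) / sum(w) * voxel_size[1],
               y_um = sum((a[, 1] - 1) * w) / sum(w) * voxel_size[2],
               z_um = sum((a[, 3] - 1) * w) / sum(w) * voxel_size[3])
  }))
  structure(list(labels = lab, voxel_size = voxel_size, table = tab),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume: %d nuclei in %s voxels\n",
              nrow(x$table), paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Link per-timepoint label volumes into cell tracks
#'
#' Greedy globally-sorted nearest-neighbour assignment between
#' consecutive timepoints: all candidate pairs within
#' `max_link_distance_um` are sorted by distance and matched one-to-one.
#' Unmatched current labels end their tracks; unmatched next labels
#' start new tracks; gaps are flagged, never interpolated or closed.
#'
#' @param label_volumes Time-ordered list of [segment_nuclei()] results
#'   (>= 2 timepoints).
#' @param max_link_distance_um Maximum centroid displacement for a link.
#' @param dt_ms Time between volumes (for the track time axis).
#' @return List of [cell_track()] objects (ordered by creation).
#' @export
link_tracks <- function(label_volumes, max_link_distance_um = 5, dt_ms = 1) {
  stopifnot(length(label_volumes) >= 2L,
            all(vapply(label_volumes, inherits, TRUE, "label_volume")))
  T_n <- length(label_volumes)
  cents <- lapply(label_volumes, function(lv)
    as.matrix(lv$table[, c("x_um", "y_um", "z_um")]))
  nvox <- lapply(label_volumes, function(lv) lv$table$n_voxels)
  ## track state: matrices indexed [track, ]
  tr_pos <- list(); tr_lab <- list(); tr_nvox <- list()
  n0 <- nrow(cents[[1]])
  active <- seq_len(n0)              # active track ids
  track_rows <- lapply(seq_len(n0), function(i) {
    m <- matrix(NA_real_, T_n, 3); m[1, ] <- cents[[1]][i, ]; m
  })
  track_lab <- lapply(seq_len(n0), function(i) {
    v <- rep(NA_integer_, T_n); v[1] <- i; v
  })
  track_vox <- lapply(seq_len(n0), function(i) {
    v <- rep(NA_real_, T_n); v[1] <- nvox[[1]][i]; v
  })
  last_pos <- cents[[1]]
  for (t in 2:T_n) {
    cur <- cents[[t]]
    n_new <- nrow(cur)
    matched_track <- rep(NA_integer_, n_new)
    if (length(active) && n_new) {
      ap <- last_pos[active, , drop = FALSE]
      dmat <- sqrt(pmax(outer(rowSums(ap^2), rowSums(cur^2), "+") -
                          2 * ap %*% t(cur), 0))
      pairs <- which(dmat <= max_link_distance_um, arr.ind = TRUE)
      if (nrow(pairs)) {
        pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
        used_a <- logical(length(active)); used_b <- logical(n_new)
        for (r in seq_len(nrow(pairs))) {
          a <- pairs[r, 1]; b <- pairs[r, 2]
          if (!used_a[a] && !used_b[b]) {
            used_a[a] <- TRUE; used_b[b] <- TRUE
            matched_track[b] <- active[a]
          }
        }
      }
    }
    new_active <- integer(0); new_last <- NULL
    for (b in seq_len(n_new)) {
      id <- matched_track[b]
      if (is.na(id)) {             # new track born at t
        track_rows[[length(track_rows) + 1L]] <- {
          m <- matrix(NA_real_, T_n, 3); m[t, ] <- cur[b, ]; m
        }
        track_lab[[length(track_lab) + 1L]] <- {
          v <- rep(NA_integer_, T_n); v[t] <- b; v
        }
        track_vox[[length(track_vox) + 1L]] <- {
          v <- rep(NA_real_, T_n); v[t] <- nvox[[t]][b]; v
        }
        id <- length(track_rows)
      } else {
        track_rows[[id]][t, ] <- cur[b, ]
        track_lab[[id]][t] <- b
        track_vox[[id]][t] <- nvox[[t]][b]
      }
      new_active <- c(new_active, id)
      new_last <- rbind(new_last, cur[b, ])
    }
    active <- new_active
    last_pos <- matrix(NA_real_, max(active, 0), 3)
    if (length(active)) last_pos[active, ] <- new_last
  }
  time_ms <- (seq_len(T_n) - 1) * dt_ms
  vv <- prod(label_volumes[[1]]$voxel_size)
  tracks <- lapply(seq_along(track_rows), function(i) {
    tr <- cell_track(cell_id = i, centroid = track_rows[[i]], time_ms = time_ms,
                     n_voxels = track_vox[[i]],
                     volume_um3 = track_vox[[i]] * vv)
    tr$label_per_t <- track_lab[[i]]
    tr
  })
  tracks
}

#' Score tracking against ground truth
#'
#' A truth cell at time `t` is correctly tracked when exactly one track
#' centroid lies within `match_radius_um` of it and that track was the
#' same one matched at `t - 1`; a cell enters `n_correct` when this holds
#' at every timepoint. False negatives are truth cells with no in-radius
#' track at one or more timepoints; false positives are tracks never
#' within radius of any truth cell.
#'
#' @param tracks List of [cell_track()] objects.
#' @param truth_positions `n_truth x 3 x T` array of ground-truth
#'   centroids (um).
#' @param match_radius_um Match radius.
#' @return Object of class `tracking_score`: `n_truth`, `n_correct`,
#'   `false_positive`, `false_negative`, `accuracy`.
#' @export
score_tracking <- function(tracks, truth_positions, match_radius_um = 2) {
  stopifnot(length(dim(truth_positions)) == 3L, dim(truth_positions)[2] == 3L)
  n_truth <- dim(truth_positions)[1]
  T_n <- dim(truth_positions)[3]
  if (!length(tracks)) {
    return(structure(list(n_truth = n_truth, n_correct = 0L,
                          false_positive = 0L, false_negative = n_truth,
                          accuracy = 0), class = "tracking_score"))
  }
  stopifnot(all(vapply(tracks, function(tr) nrow(tr$centroid), 0L) == T_n))
  track_used <- rep(FALSE, length(tracks))
  correct <- rep(TRUE, n_truth)
  missing <- rep(FALSE, n_truth)
  cent <- lapply(tracks, `[[`, "centroid")
  for (i in seq_len(n_truth)) {
    prev_match <- NA_integer_
    for (t in seq_len(T_n)) {
      p <- truth_positions[i, , t]
      dists <- vapply(cent, function(cm) {
        if (anyNA(cm[t, ])) Inf else sqrt(sum((cm[t, ] - p)^2))
      }, 0)
      inr <- which(dists <= match_radius_um)
      if (length(inr)) track_used[inr] <- TRUE
      if (length(inr) != 1L) {
        correct[i] <- FALSE
        if (!length(inr)) missing[i] <- TRUE
      } else {
        if (t > 1L && !is.na(prev_match) && inr != prev_match) correct[i] <- FALSE
        prev_match <- inr
      }
      if (length(inr) != 1L) prev_match <- NA_integer_
    }
  }
  structure(list(n_truth = n_truth,
                 n_correct = sum(correct),
                 false_positive = sum(!track_used),
                 false_negative = sum(missing),
                 accuracy = sum(correct) / n_truth),
            class = "tracking_score")
}

#' @export
print.tracking_score <- function(x, ...) {
  cat(sprintf("Tracking: %d/%d cells correct (%.1f%%), FP = %d, FN = %d\n",
              x$n_correct, x$n_truth, 100 * x$accuracy,
              x$false_positive, x$false_negative))
  invisible(x)
}

#' Assign an anatomical region to a track
#'
#' Majority vote of the labelled region mask sampled at the track's
#' centroid over all timepoints; `"unassigned"` when the centroid falls
#' outside every mask more than half the time.
#'
#' @param track A [cell_track()].
#' @param region_masks Integer array `[y, x, z]` (1 = ventricle,
#'   2 = atrium, 3 = AVC, 0 = none), e.g. [phantom_region_masks()].
#' @param voxel_size `(x, y, z)` voxel size (um).
#' @return The region label string.
#' @export
assign_region <- function(track, region_masks, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(track, "cell_track"))
  d <- dim(region_masks)
  codes <- apply(track$centroid, 1, function(p) {
    if (anyNA(p)) return(NA_integer_)
    j <- round(p[1] / voxel_size[1]) + 1
    i <- round(p[2] / voxel_size[2]) + 1
    k <- round(p[3] / voxel_size[3]) + 1
    if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3])
      return(0L)
    region_masks[i, j, k]
  })
  codes <- codes[!is.na(codes)]
  if (!length(codes)) return("unassigned")
  if (sum(codes == 0L) > length(codes) / 2) return("unassigned")
  inside <- codes[codes > 0L]
  win <- as.integer(names(which.max(table(inside))))
  c("ventricle", "atrium", "AVC")[win]
}
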