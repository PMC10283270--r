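## Synthetic beating-heart phantom.
##
## Emulates slice-by-slice light-sheet acquisition of a quasi-periodic
## heart: each axial slice is recorded as its own time-lapse starting at an
## unknown cardiac phase, with optional per-cycle period jitter and
## additive noise. Geometry: two ellipsoidal shells (ventricle, atrium)
## joined by an atrioventricular-canal ring, nuclei fixed on the shells,
## shell radii driven by a raised-cosine contraction waveform anti-phased
## between the chambers. All stochastic draws run off named substreams of
## one seed so that e.g. adding noise never perturbs the geometry draw.

.stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562 + 1)
}

#' Phantom configuration
#'
#' Defaults reproduce the acquisition geometry the package targets: 300
#' frames per Z-movie at 200 fps covering 3.75 cycles of a 400 ms
#' heartbeat, 1 um axial step. The spatial scene is a miniature
#' two-chamber heart (a few tens of micrometres) so that full series
#' render in seconds; see the methods vignette for what the phantom does
#' and does not emulate.
#'
#' @param n_slices Number of axial slices (Z-movies).
#' @param n_frames Frames per Z-movie (must cover >= 3 cardiac cycles).
#' @param frame_rate Acquisition frame rate (fps).
#' @param period_ms Mean cardiac period in milliseconds.
#' @param period_jitter_frac Fractional standard deviation of per-cycle
#'   period (0.01 emulates the ~1 percent beat-to-beat variability of the
#'   larval zebrafish heart).
#' @param phase_offsets Per-slice starting cardiac phase in `[0, 1)`:
#'   a numeric vector, `"random"` (uniform on `[0, 1)`) or
#'   `"random_grid"` (uniform on the frame grid `k/P`, which makes exact
#'   frame-level phase recovery well defined).
#' @param n_nuclei Total nuclei on the two shells plus the AVC ring.
#' @param nucleus_sigma_um Gaussian radius of a rendered nucleus (um).
#' @param contraction_amplitude Fractional ventricular radius change from
#'   end-diastole to end-systole, in `[0, 0.5)`.
#' @param atrial_amplitude_factor Atrial amplitude as a multiple of the
#'   ventricular one (> 1 mirrors the larger atrial displacement).
#' @param noise_sigma Additive Gaussian intensity noise (counts).
#' @param psf_sigma_um Length-2 `(lateral, axial)` Gaussian blur of the
#'   emulated detection PSF (um).
#' @param pixel_size_xy,step_size_z Voxel geometry (um).
#' @param frame_size `(height, width)` of each frame in pixels.
#' @param intensity Peak intensity scale of a unit-brightness nucleus.
#' @param min_nucleus_separation_um Enforced pairwise nucleus separation
#'   at end-diastole.
#' @param n_ref_phases Number of noise-free ground-truth volumes sampled
#'   over one canonical cycle; defaults to the frames-per-period count.
#' @param seed Integer seed driving all named random substreams.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 20L,
                           n_frames = 300L,
                           frame_rate = 200,
                           period_ms = 400,
                           period_jitter_frac = 0,
                           phase_offsets = "random",
                           n_nuclei = 40L,
                           nucleus_sigma_um = 1.2,
                           contraction_amplitude = 0.15,
                           atrial_amplitude_factor = 1.5,
                           noise_sigma = 0,
                           psf_sigma_um = c(0.535, 1.053),
                           pixel_size_xy = 1,
                           step_size_z = 1,
                           frame_size = c(48L, 48L),
                           intensity = 3000,
                           min_nucleus_separation_um = 4,
                           n_ref_phases = NULL,
                           seed = 1L) {
  E <- 1000 / frame_rate
  P <- period_ms / E
  stopifnot(n_slices >= 1, n_frames >= 2, frame_rate > 0, period_ms > 0,
            period_jitter_frac >= 0,
            n_nuclei >= 0, nucleus_sigma_um > 0,
            contraction_amplitude >= 0, contraction_amplitude < 0.5,
            atrial_amplitude_factor > 0,
            noise_sigma >= 0, length(psf_sigma_um) == 2L,
            pixel_size_xy > 0, step_size_z > 0, length(frame_size) == 2L,
            intensity > 0)
  if (n_frames < 3 * P)
    stop(sprintf("n_frames (%d) must cover at least 3 cardiac cycles (3 x %.3g frames)",
                 n_frames, P))
  if (is.numeric(phase_offsets)) {
    stopifnot(length(phase_offsets) == n_slices,
              all(phase_offsets >= 0), all(phase_offsets < 1))
  } else stopifnot(phase_offsets %in% c("random", "random_grid"))
  if (is.null(n_ref_phases)) n_ref_phases <- as.integer(round(P))
  structure(list(n_slices = as.integer(n_slices),
                 n_frames = as.integer(n_frames),
                 frame_rate = frame_rate, period_ms = period_ms,
                 period_jitter_frac = period_jitter_frac,
                 phase_offsets = phase_offsets,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_sigma_um = nucleus_sigma_um,
                 contraction_amplitude = contraction_amplitude,
                 atrial_amplitude_factor = atrial_amplitude_factor,
                 noise_sigma = noise_sigma,
                 psf_sigma_um = as.numeric(psf_sigma_um),
                 pixel_size_xy = pixel_size_xy, step_size_z = step_size_z,
                 frame_size = as.integer(frame_size),
                 intensity = intensity,
                 min_nucleus_separation_um = min_nucleus_separation_um,
                 n_ref_phases = as.integer(n_ref_phases),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  P <- x$period_ms * x$frame_rate / 1000
  cat(sprintf("Phantom: %d slices x %d frames @ %g fps; period %g ms (P = %.3g frames, %.2f cycles/movie)\n",
              x$n_slices, x$n_frames, x$frame_rate, x$period_ms, P, x$n_frames / P))
  cat(sprintf("  %d nuclei, contraction %.2g (atrium x%.2g), jitter %.2g, noise %.3g\n",
              x$n_nuclei, x$contraction_amplitude, x$atrial_amplitude_factor,
              x$period_jitter_frac, x$noise_sigma))
  invisible(x)
}

.phantom_meta <- function(config) {
  acquisition_meta(frame_rate = config$frame_rate,
                   pixel_size_xy = config$pixel_size_xy,
                   step_size_z = config$step_size_z,
                   bit_depth = 16L)
}

## Static scene layout shared by all phases: chamber centres/semi-axes in
## um, per-nucleus unit direction, region, brightness. Deterministic in
## (config$seed); uses the "geometry" stream only.
.heart_static <- function(config) {
  X <- config$frame_size[2] * config$pixel_size_xy
  Y <- config$frame_size[1] * config$pixel_size_xy
  Z <- config$n_slices * config$step_size_z
  ## chamber z-extent spans (nearly) the whole stack: every recorded
  ## slice images cardiac content, as in an acquisition that scans the
  ## heart volume
  chambers <- list(
    ventricle = list(center = c(0.50 * X, 0.33 * Y, 0.50 * Z),
                     semi   = c(0.21 * X, 0.19 * Y, 0.46 * Z)),
    atrium    = list(center = c(0.50 * X, 0.71 * Y, 0.50 * Z),
                     semi   = c(0.18 * X, 0.16 * Y, 0.43 * Z)))
  avc <- list(center = c(0.50 * X, 0.515 * Y, 0.50 * Z),
              radius = min(0.09 * X, 0.35 * Z))
  n <- config$n_nuclei
  n_v <- round(0.45 * n); n_a <- round(0.45 * n); n_c <- n - n_v - n_a
  ## AVC nuclei go first: their narrow ring would otherwise be crowded out
  ## by shell nuclei near the chamber poles
  region <- rep(c("AVC", "ventricle", "atrium"), c(n_c, n_v, n_a))

  amp_v <- config$contraction_amplitude
  amp_a <- min(0.49, amp_v * config$atrial_amplitude_factor)
  shrink <- 1 - max(amp_v, amp_a)   # worst-case radial contraction
  min_sep <- config$min_nucleus_separation_um / shrink

  set.seed(.stream_seed(config$seed, "geometry"))
  dirs <- matrix(NA_real_, n, 3)
  pos0 <- matrix(NA_real_, n, 3)    # end-diastole positions
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 4000L * max(n, 1L))
      stop("cannot place nuclei at the required separation; reduce n_nuclei or separation")
    i <- placed + 1L
    if (region[i] == "AVC") {
      th <- runif(1, 0, 2 * pi)
      d <- c(cos(th), runif(1, -0.15, 0.15), sin(th))
      p <- avc$center + avc$radius * c(d[1], 0, d[3]) + c(0, d[2] * 2, 0)
    } else {
      v <- rnorm(3); v <- v / sqrt(sum(v^2))
      ch <- chambers[[region[i]]]
      d <- v
      p <- ch$center + ch$semi * v
    }
    if (placed == 0L || min(sqrt(colSums((t(pos0[seq_len(placed), , drop = FALSE]) - p)^2))) >= min_sep) {
      placed <- i
      dirs[i, ] <- d
      pos0[i, ] <- p
    }
  }
  brightness <- runif(n, 0.7, 1.3)

  sig_lat <- sqrt(config$nucleus_sigma_um^2 + config$psf_sigma_um[1]^2)
  sig_ax <- sqrt(config$nucleus_sigma_um^2 + config$psf_sigma_um[2]^2)
  pad <- 3.5 * sig_lat
  if (n > 0 && (min(pos0[, 1]) < pad || max(pos0[, 1]) > X - pad ||
                min(pos0[, 2]) < pad || max(pos0[, 2]) > Y - pad ||
                min(pos0[, 3]) < 0 || max(pos0[, 3]) > Z))
    stop("phantom geometry leaves the field of view; enlarge frame_size/n_slices")

  list(chambers = chambers, avc = avc, region = region, dirs = dirs,
       brightness = brightness, amp_v = amp_v, amp_a = amp_a,
       sigma_lateral = sig_lat, sigma_axial = sig_ax,
       fov = c(X, Y, Z))
}

## Raised-cosine contraction waveform with a monotone phase warp that
## makes systole faster than diastole (as in a real cardiac cycle). The
## warp also removes the phase-reflection symmetry a plain cosine would
## have, so distinct phases never render identically.
.contraction_w <- function(phase, asymmetry = 0.35) {
  p <- phase %% 1
  u <- p + asymmetry * (1 - cos(2 * pi * p)) / (2 * pi)
  (1 - cos(2 * pi * u)) / 2
}

## Nucleus centres (um) at a given cardiac phase.
.heart_positions <- function(static, phase) {
  s_v <- 1 - static$amp_v * .contraction_w(phase)
  s_a <- 1 - static$amp_a * .contraction_w(phase + 0.5)
  s_c <- 1 - 0.4 * static$amp_v * .contraction_w(phase)
  n <- length(static$region)
  pos <- matrix(NA_real_, n, 3)
  for (rg in c("ventricle", "atrium")) {
    idx <- static$region == rg
    if (!any(idx)) next
    ch <- static$chambers[[rg]]
    s <- if (rg == "ventricle") s_v else s_a
    pos[idx, ] <- rep(ch$center, each = sum(idx)) +
      static$dirs[idx, , drop = FALSE] *
      rep(ch$semi * s, each = sum(idx))
  }
  idx <- static$region == "AVC"
  if (any(idx)) {
    d <- static$dirs[idx, , drop = FALSE]
    ctr <- static$avc$center
    pos[idx, ] <- cbind(ctr[1] + static$avc$radius * s_c * d[, 1],
                        ctr[2] + d[, 2] * 2,
                        ctr[3] + static$avc$radius * s_c * d[, 3])
  }
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' Evaluate the phantom heart scene at one cardiac phase
#'
#' Returns the nucleus positions (micrometres), regions and brightness of
#' the two-chamber phantom at a phase in `[0, 1)`. Deterministic for a
#' given `(config, phase)`; nucleus counts per region are fixed across
#' phases (no birth or death).
#'
#' @param config A [phantom_config()].
#' @param phase Cardiac phase in `[0, 1)` (phase 0 = end-diastole of the
#'   ventricle under the raised-cosine waveform).
#' @return A data.frame with columns `x`, `y`, `z`, `region`,
#'   `brightness`, carrying the blur widths as attributes.
#' @export
heart_geometry <- function(config, phase) {
  stopifnot(inherits(config, "phantom_config"), phase >= 0, phase < 1)
  static <- .heart_static(config)
  pos <- .heart_positions(static, phase)
  scene <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      region = static$region, brightness = static$brightness)
  attr(scene, "sigma_lateral") <- static$sigma_lateral
  attr(scene, "sigma_axial") <- static$sigma_axial
  scene
}

## Core rasterizer: anisotropically blurred blobs intersecting one slice.
.render_scene_slice <- function(scene, z_um, config, sigma_lat, sigma_ax,
                                noise_sigma = 0) {
  h <- config$frame_size[1]; w <- config$frame_size[2]
  px <- config$pixel_size_xy
  img <- matrix(0, h, w)
  if (nrow(scene)) {
    xg <- (seq_len(w) - 1) * px
    yg <- (seq_len(h) - 1) * px
    keep <- abs(scene$z - z_um) <= 3.5 * sigma_ax
    for (i in which(keep)) {
      az <- exp(-(scene$z[i] - z_um)^2 / (2 * sigma_ax^2))
      a <- config$intensity * scene$brightness[i] * az
      r <- 3.5 * sigma_lat
      jx <- which(abs(xg - scene$x[i]) <= r)
      jy <- which(abs(yg - scene$y[i]) <= r)
      if (!length(jx) || !length(jy)) next
      gx <- exp(-(xg[jx] - scene$x[i])^2 / (2 * sigma_lat^2))
      gy <- exp(-(yg[jy] - scene$y[i])^2 / (2 * sigma_lat^2))
      img[jy, jx] <- img[jy, jx] + a * outer(gy, gx)
    }
  }
  if (noise_sigma > 0)
    img <- img + matrix(rnorm(h * w, sd = noise_sigma), h, w)
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}

#' Render one axial slice of a phantom scene
#'
#' Sums anisotropically blurred Gaussian blobs intersecting the slice and
#' (optionally) adds Gaussian noise from the current RNG state. With
#' `noise_sigma = 0` the render is a pure deterministic function of
#' `(scene, z_index)`.
#'
#' @param scene Output of [heart_geometry()].
#' @param z_index 0-based slice index.
#' @param config The [phantom_config()] the scene came from.
#' @param noise_sigma Additive noise level; defaults to the config value.
#' @return An `h x w` integer-valued intensity matrix.
#' @export
render_slice <- function(scene, z_index, config, noise_sigma = config$noise_sigma) {
  stopifnot(z_index >= 0, z_index < config$n_slices)
  .render_scene_slice(scene, z_index * config$step_size_z, config,
                      attr(scene, "sigma_lateral"), attr(scene, "sigma_axial"),
                      noise_sigma)
}

## Starting phases for all slices (uses the "phases" stream).
.draw_phase_offsets <- function(config) {
  if (is.numeric(config$phase_offsets)) return(config$phase_offsets)
  set.seed(.stream_seed(config$seed, "phases"))
  if (identical(config$phase_offsets, "random_grid")) {
    P <- as.integer(round(config$period_ms * config$frame_rate / 1000))
    (sample.int(P, config$n_slices, replace = TRUE) - 1L) / P
  } else runif(config$n_slices)
}

## Per-slice cardiac phase at every frame. Returns list(phase = vector of
## phases in [0,1), periods_ms = realized per-cycle periods). With zero
## jitter and an integer frames-per-period the computation is arranged so
## that frame t and frame t + P yield bit-identical phases.
.slice_phases <- function(config, offset, slice_seed) {
  E <- 1000 / config$frame_rate
  t_idx <- seq_len(config$n_frames) - 1
  P_real <- config$period_ms / E
  if (config$period_jitter_frac == 0) {
    if (abs(P_real - round(P_real)) < 1e-9) {
      P <- round(P_real)
      phase <- (offset + (t_idx %% P) / P) %% 1
    } else phase <- (offset + t_idx / P_real) %% 1
    return(list(phase = phase, periods_ms = config$period_ms))
  }
  n_cycles <- ceiling(config$n_frames * E / config$period_ms) + 3L
  set.seed(slice_seed)
  periods <- config$period_ms * pmax(0.5, 1 + config$period_jitter_frac * rnorm(n_cycles))
  bounds <- c(0, cumsum(periods))
  tau <- t_idx * E
  k <- findInterval(tau, bounds, rightmost.closed = FALSE) # cycle index, 1-based
  phase <- (offset + (k - 1) + (tau - bounds[k]) / periods[k]) %% 1
  list(phase = phase, periods_ms = periods)
}

#' Generate a synthetic Z-movie series with ground truth
#'
#' Emulates the slice-by-slice acquisition: slice `z`'s movie renders the
#' heart at a phase advancing from the slice's own starting phase with
#' per-cycle jittered periods. Identical `(config, seed)` yields
#' bit-identical output.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `series` (a [zstack_series()]) and
#'   `truth` (class `phantom_truth`): per-slice starting phases, realized
#'   periods, per-nucleus trajectories vs. phase, region labels, and
#'   noise-free reference volumes on one canonical cycle.
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  static <- .heart_static(config)
  meta <- .phantom_meta(config)
  offsets <- .draw_phase_offsets(config)
  z_um <- (seq_len(config$n_slices) - 1) * config$step_size_z

  movies <- vector("list", config$n_slices)
  periods <- vector("list", config$n_slices)
  phase_mat <- matrix(NA_real_, config$n_slices, config$n_frames)
  for (z in seq_len(config$n_slices)) {
    ph <- .slice_phases(config, offsets[z],
                        .stream_seed(config$seed, paste0("periods", z)))
    periods[[z]] <- ph$periods_ms
    phase_mat[z, ] <- ph$phase
    set.seed(.stream_seed(config$seed, paste0("noise", z)))
    frames <- array(0, c(config$frame_size, config$n_frames))
    for (t in seq_len(config$n_frames)) {
      scene_pos <- .heart_positions(static, ph$phase[t])
      scene <- data.frame(x = scene_pos[, 1], y = scene_pos[, 2],
                          z = scene_pos[, 3],
                          region = static$region, brightness = static$brightness)
      frames[, , t] <- .render_scene_slice(scene, z_um[z], config,
                                           static$sigma_lateral, static$sigma_axial,
                                           config$noise_sigma)
    }
    movies[[z]] <- zmovie(frames, z_index = z - 1L, meta = meta)
  }

  K <- config$n_ref_phases
  ref_phases <- (seq_len(K) - 1) / K
  traj <- array(NA_real_, c(config$n_nuclei, 3, K))
  ref_vols <- vector("list", K)
  for (k in seq_len(K)) {
    pos <- .heart_positions(static, ref_phases[k])
    traj[, , k] <- pos
    vol <- array(0, c(config$frame_size, config$n_slices))
    scene <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        region = static$region, brightness = static$brightness)
    for (z in seq_len(config$n_slices))
      vol[, , z] <- .render_scene_slice(scene, z_um[z], config,
                                        static$sigma_lateral, static$sigma_axial, 0)
    ref_vols[[k]] <- vol
  }

  truth <- structure(list(
    phase_offsets = offsets,
    periods_ms = periods,
    phase_at_frame = phase_mat,
    regions = static$region,
    trajectories = traj,        # n_nuclei x 3 x n_ref_phases, um
    ref_phases = ref_phases,
    reference_volumes = ref_vols,
    position = function(phase) .heart_positions(static, phase %% 1),
    static = static,
    config = config), class = "phantom_truth")
  list(series = zstack_series(movies, meta), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom truth: %d slices, %d nuclei (%s), %d reference phases\n",
              length(x$phase_offsets), length(x$regions),
              paste(sprintf("%s=%d", names(table(x$regions)), table(x$regions)),
                    collapse = ", "),
              length(x$ref_phases)))
  invisible(x)
}

#' Region masks of the phantom at a reference phase
#'
#' Labels every voxel inside the (slightly dilated) ventricle, atrium or
#' AVC neck of the phantom geometry: 1 = ventricle, 2 = atrium, 3 = AVC,
#' 0 = background. Used to annotate tracks via [assign_region()].
#'
#' @param config A [phantom_config()].
#' @param phase Cardiac phase of the mask (default end-diastole, 0).
#' @param dilate_um Radial dilation so shell-surface nuclei fall inside.
#' @return Integer array `h x w x n_slices`.
#' @export
phantom_region_masks <- function(config, phase = 0, dilate_um = 2.5) {
  static <- .heart_static(config)
  h <- config$frame_size[1]; w <- config$frame_size[2]; nz <- config$n_slices
  xg <- (seq_len(w) - 1) * config$pixel_size_xy
  yg <- (seq_len(h) - 1) * config$pixel_size_xy
  zg <- (seq_len(nz) - 1) * config$step_size_z
  mask <- array(0L, c(h, w, nz))
  co <- expand.grid(y = yg, x = xg, z = zg)
  s_v <- 1 - static$amp_v * .contraction_w(phase)
  s_a <- 1 - static$amp_a * .contraction_w(phase + 0.5)
  scales <- c(ventricle = s_v, atrium = s_a)
  for (rg in c("ventricle", "atrium")) {
    ch <- static$chambers[[rg]]
    semi <- ch$semi * scales[[rg]] + dilate_um
    r2 <- ((co$x - ch$center[1]) / semi[1])^2 +
      ((co$y - ch$center[2]) / semi[2])^2 +
      ((co$z - ch$center[3]) / semi[3])^2
    mask[r2 <= 1] <- if (rg == "ventricle") 1L else 2L
  }
  ctr <- static$avc$center
  rad <- sqrt((co$x - ctr[1])^2 + (co$z - ctr[3])^2)
  in_avc <- abs(rad - static$avc$radius) <= dilate_um &
    abs(co$y - ctr[2]) <= (2 + dilate_um)
  mask[in_avc] <- 3L
  mask
}

#' Generate a synthetic bead volume for PSF calibration
#'
#' Places `n_beads` anisotropic Gaussian beads (sigma = FWHM / 2.3548) at
#' sub-voxel positions with pairwise separation of at least
#' `separation_factor` times the largest FWHM, enforced by rejection
#' sampling.
#'
#' @param n_beads Number of beads.
#' @param fwhm_lateral_um,fwhm_axial_um Generated FWHMs (um).
#' @param volume_shape `(h, w, nz)` voxels.
#' @param voxel_size `(x, y, z)` voxel size (um).
#' @param seed Integer seed.
#' @param separation_factor Minimum pairwise separation in FWHM units.
#' @param intensity Mean peak amplitude (beads vary 0.5-1x).
#' @return List with `volume` (3D array) and `centers` (n x 3 matrix of
#'   sub-voxel `(x, y, z)` positions in voxel units, 0-based).
#' @export
generate_beads <- function(n_beads, fwhm_lateral_um = 1.26, fwhm_axial_um = 2.48,
                           volume_shape = c(256L, 256L, 75L),
                           voxel_size = c(0.325, 0.325, 1),
                           seed = 1L, separation_factor = 5,
                           intensity = 10000) {
  k <- 2 * sqrt(2 * log(2))
  sig_um <- c(fwhm_lateral_um, fwhm_lateral_um, fwhm_axial_um) / k
  sig_vox <- sig_um / voxel_size   # (x, y, z)
  vol <- array(0, volume_shape)
  centers <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  if (n_beads == 0) return(list(volume = vol, centers = centers))
  min_sep_um <- separation_factor * max(fwhm_lateral_um, fwhm_axial_um)
  margin <- pmax(9, ceiling(4 * sig_vox)) + 1   # keep fit windows in-volume
  set.seed(seed)
  pos <- matrix(NA_real_, n_beads, 3)
  placed <- 0L; tries <- 0L
  lim <- c(volume_shape[2], volume_shape[1], volume_shape[3]) - 1  # x, y, z
  while (placed < n_beads) {
    tries <- tries + 1L
    if (tries > 20000L * n_beads)
      stop("cannot place ", n_beads, " beads at the required separation")
    p <- c(runif(1, margin[1], lim[1] - margin[1]),
           runif(1, margin[2], lim[2] - margin[2]),
           runif(1, margin[3], lim[3] - margin[3]))
    p_um <- p * voxel_size
    ok <- placed == 0L ||
      min(sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE] ) * voxel_size - p_um)^2))) >= min_sep_um
    if (ok) { placed <- placed + 1L; pos[placed, ] <- p }
  }
  amp <- intensity * runif(n_beads, 0.5, 1)
  for (i in seq_len(n_beads)) {
    cx <- pos[i, 1]; cy <- pos[i, 2]; cz <- pos[i, 3]
    jx <- max(1, floor(cx - 4 * sig_vox[1])):min(volume_shape[2], ceiling(cx + 4 * sig_vox[1]) + 1)
    jy <- max(1, floor(cy - 4 * sig_vox[2])):min(volume_shape[1], ceiling(cy + 4 * sig_vox[2]) + 1)
    jz <- max(1, floor(cz - 4 * sig_vox[3])):min(volume_shape[3], ceiling(cz + 4 * sig_vox[3]) + 1)
    gx <- exp(-((jx - 1) - cx)^2 / (2 * sig_vox[1]^2))
    gy <- exp(-((jy - 1) - cy)^2 / (2 * sig_vox[2]^2))
    gz <- exp(-((jz - 1) - cz)^2 / (2 * sig_vox[3]^2))
    blob <- outer(outer(gy, gx), gz)
    vol[jy, jx, jz] <- vol[jy, jx, jz] + amp[i] * blob
  }
  vol <- round(vol)
  colnames(pos) <- c("x", "y", "z")
  list(volume = vol, centers = pos)
}

#' Construct an adversarial three-movie series with a spurious pairwise optimum
#'
#' Builds three synthetic Z-movies in which the middle slice renders two
#' distinct cardiac phases near-identically against its predecessor: its
#' content shared with slice 1 carries a slightly stronger "echo" at a
#' false phase, while its content shared with slice 3 pulses at the true
#' phase. Two-movie SSD alignment therefore locks onto the false phase,
#' whereas the triple-movie comparison (adding first-third and
#' second-third scores) recovers the truth. Used to exercise the
#' anti-local-optimum behaviour of [align_series()].
#'
#' @param P Cycle length in frames.
#' @param n_frames Frames per movie (>= `4 * P`).
#' @param true_offsets Integer length-3 true phase offsets (frames) of the
#'   three movies; the first must be 0.
#' @param false_offset Frame offset (relative to movie 1) at which the
#'   middle movie's echo sits; must differ from `true_offsets[2]`.
#' @return List with `series` (a [zstack_series()]) and `truth`
#'   (list of the designed offsets).
#' @export
adversarial_series <- function(P = 20L, n_frames = 100L,
                               true_offsets = c(0L, 5L, 13L),
                               false_offset = 11L) {
  stopifnot(n_frames >= 4 * P, true_offsets[1] == 0L,
            false_offset != true_offsets[2])
  h <- 16L; w <- 32L
  blob <- function(cx, cy) {
    outer(exp(-((1:h) - cy)^2 / (2 * 2^2)), exp(-((1:w) - cx)^2 / (2 * 2^2)))
  }
  U <- blob(8, 8); W <- blob(24, 8)       # orthogonal spatial patterns
  pulse <- function(offset) {             # periodic temporal envelope
    t_idx <- 0:(n_frames - 1)
    d <- (t_idx - offset) %% P
    d <- pmin(d, P - d)
    exp(-d^2 / 2)
  }
  build <- function(amp_u, off_u, amp_w, off_w, z, amp_u2 = 0, off_u2 = 0) {
    env_u <- amp_u * pulse(off_u)
    if (amp_u2 > 0) env_u <- env_u + amp_u2 * pulse(off_u2)
    env_w <- amp_w * pulse(off_w)
    frames <- array(0, c(h, w, n_frames))
    for (t in seq_len(n_frames))
      frames[, , t] <- round(1000 * (env_u[t] * U + env_w[t] * W))
    zmovie(frames, z_index = z, meta = acquisition_meta(frame_rate = 200,
                                                        pixel_size_xy = 1))
  }
  ## amplitudes balanced so the pairwise 1<->2 optimum sits at the echo
  ## (false) phase while both cross terms against movie 3 are strong
  ## enough that no consistent offset pair can rescue it
  m1 <- build(1.5, 0, 0, 0, 0L)
  m2 <- build(0.9, false_offset, 2.0, true_offsets[2], 1L)
  m3 <- build(1.5, true_offsets[3], 2.0, true_offsets[3], 2L)
  list(series = zstack_series(list(m1, m2, m3)),
       truth = list(offsets = as.integer(true_offsets), P = as.integer(P),
                    false_offset = as.integer(false_offset)))
}
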