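# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 20-slice, 150-frame noise-free phantom with grid-aligned random phases
# (P = 30 frames, 5 cycles per movie)
grid_phantom <- function(seed = 5) {
  cached(paste0("grid", seed), {
    cfg <- phantom_config(n_slices = 20, n_frames = 150, frame_rate = 200,
                          period_ms = 150, phase_offsets = "random_grid",
                          n_nuclei = 30, seed = seed)
    c(generate_series(cfg), list(config = cfg, P = 30L))
  })
}

# same acquisition with 1% period jitter, 5% intensity noise, continuous phases
jitter_phantom <- function(seed) {
  cfg <- phantom_config(n_slices = 20, n_frames = 150, frame_rate = 200,
                        period_ms = 150, phase_offsets = "random",
                        period_jitter_frac = 0.01, noise_sigma = 150,
                        n_nuclei = 30, seed = seed)
  c(generate_series(cfg), list(config = cfg, P = 30L))
}

# small static-geometry phantom for segmentation/tracking (16 reference
# phases, nuclei kept >= 4 blur sigmas apart through the whole cycle)
easy_track_phantom <- function(seed = 2, amplitude = 0.08) {
  cached(paste0("easy", seed, "_", amplitude), {
    cfg <- phantom_config(n_slices = 20, n_frames = 150, period_ms = 150,
                          phase_offsets = rep(0, 20), n_nuclei = 25,
                          contraction_amplitude = amplitude,
                          min_nucleus_separation_um = 5.5,
                          n_ref_phases = 16, seed = seed)
    sim <- generate_series(cfg)
    labs <- lapply(sim$truth$reference_volumes, segment_nuclei,
                   min_seed_separation_um = 3, min_voxels = 5)
    c(sim, list(config = cfg, labels = labs))
  })
}

# ground-truth per-slice offsets (frames) under jitter: the frame of each
# movie whose realized phase matches the reference movie's phase at frame 0
expected_offsets <- function(truth, P) {
  ph <- truth$phase_at_frame
  target <- ph[1, 1]
  vapply(seq_len(nrow(ph)), function(z) {
    cd <- pmin(abs(ph[z, 1:P] - target), 1 - abs(ph[z, 1:P] - target))
    which.min(cd) - 1L
  }, 0L)
}

circ_dist <- function(a, b, P) {
  d <- (a - b) %% P
  pmin(d, P - d)
}

# voxelized analytic shapes wrapped as label volumes
shape_label_volume <- function(mask, voxel_size) {
  structure(list(labels = array(as.integer(mask), dim(mask)),
                 voxel_size = voxel_size,
                 table = data.frame(label = 1L, n_voxels = sum(mask),
                                    x_um = NA, y_um = NA, z_um = NA)),
            class = "label_volume")
}

voxel_sphere <- function(r_vox, n = 2 * r_vox + 7) {
  ctr <- (n + 1) / 2
  g <- expand.grid(seq_len(n), seq_len(n), seq_len(n))
  array((g[, 1] - ctr)^2 + (g[, 2] - ctr)^2 + (g[, 3] - ctr)^2 <= r_vox^2,
        c(n, n, n))
}
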