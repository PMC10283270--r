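test_that("identical config and seed give bit-identical series and truth", {
  cfg <- phantom_config(n_slices = 4, n_frames = 24, period_ms = 40,
                        n_nuclei = 8, frame_size = c(32L, 32L),
                        noise_sigma = 50, period_jitter_frac = 0.01,
                        seed = 42)
  a <- generate_series(cfg)
  b <- generate_series(cfg)
  expect_identical(lapply(a$series$movies, `[[`, "frames"),
                   lapply(b$series$movies, `[[`, "frames"))
  expect_identical(a$truth$phase_offsets, b$truth$phase_offsets)
  expect_identical(a$truth$trajectories, b$truth$trajectories)
})

test_that("jitter-free movies are exactly periodic: frame(t) == frame(t + P)", {
  sim <- grid_phantom()
  P <- sim$P
  for (z in c(1, 10, 20)) {
    f <- sim$series$movies[[z]]$frames
    expect_identical(f[, , 1:30], f[, , (P + 1):(P + 30)])
  }
})

test_that("scene geometry is deterministic and respects degenerate settings", {
  cfg <- phantom_config(n_slices = 10, n_frames = 30, period_ms = 50,
                        n_nuclei = 10, seed = 9)
  expect_identical(heart_geometry(cfg, 0.3), heart_geometry(cfg, 0.3))
  cfg0 <- phantom_config(n_slices = 10, n_frames = 30, period_ms = 50,
                         n_nuclei = 10, contraction_amplitude = 0, seed = 9)
  expect_identical(heart_geometry(cfg0, 0.0)[, c("x", "y", "z")],
                   heart_geometry(cfg0, 0.5)[, c("x", "y", "z")])
})

test_that("ventricular shell radius follows the contraction waveform analytically", {
  amp <- 0.2
  cfg <- phantom_config(n_slices = 10, n_frames = 30, period_ms = 50,
                        n_nuclei = 20, contraction_amplitude = amp, seed = 4)
  s0 <- heart_geometry(cfg, 0)
  s5 <- heart_geometry(cfg, 0.5)
  # independent evaluation of the documented waveform: raised cosine of a
  # monotone warped phase u = p + 0.35 (1 - cos 2 pi p) / (2 pi)
  w <- function(p) {
    u <- (p %% 1) + 0.35 * (1 - cos(2 * pi * (p %% 1))) / (2 * pi)
    (1 - cos(2 * pi * u)) / 2
  }
  expected_ratio <- (1 - amp * w(0.5)) / (1 - amp * w(0))
  iv <- which(s0$region == "ventricle")
  ctr <- beatsync:::.heart_static(cfg)$chambers$ventricle$center
  d0 <- sqrt(rowSums((s0[iv, c("x", "y", "z")] - rep(ctr, each = length(iv)))^2))
  d5 <- sqrt(rowSums((s5[iv, c("x", "y", "z")] - rep(ctr, each = length(iv)))^2))
  expect_equal(unname(d5 / d0), rep(expected_ratio, length(iv)), tolerance = 1e-12)
})

test_that("random starting phases are uniform on [0, 1)", {
  cfg <- phantom_config(n_slices = 200, n_frames = 30, period_ms = 50,
                        n_nuclei = 0, phase_offsets = "random", seed = 31)
  off <- beatsync:::.draw_phase_offsets(cfg)
  expect_length(off, 200)
  ks <- suppressWarnings(stats::ks.test(off, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rendering is linear and empty scenes render to zero", {
  cfg <- phantom_config(n_slices = 10, n_frames = 30, period_ms = 50,
                        n_nuclei = 10, seed = 4)
  scene <- heart_geometry(cfg, 0.2)
  expect_true(all(render_slice(scene[0, ], 3, cfg, noise_sigma = 0) == 0))
  img1 <- render_slice(scene, 3, cfg, noise_sigma = 0)
  scene2 <- scene
  scene2$brightness <- 2 * scene$brightness
  img2 <- render_slice(scene2, 3, cfg, noise_sigma = 0)
  expect_lte(max(abs(img2 - 2 * img1)), 2)  # linear up to integer rounding
})

test_that("a nucleus centred on a slice renders with its maximum at the nucleus", {
  cfg <- phantom_config(n_slices = 10, n_frames = 30, period_ms = 50,
                        n_nuclei = 10, seed = 4)
  scene <- data.frame(x = 20, y = 30, z = 3, region = "ventricle",
                      brightness = 1)
  attr(scene, "sigma_lateral") <- attr(heart_geometry(cfg, 0), "sigma_lateral")
  attr(scene, "sigma_axial") <- attr(heart_geometry(cfg, 0), "sigma_axial")
  img <- render_slice(scene, 3, cfg, noise_sigma = 0)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(30 + 1, 20 + 1))  # row = y, col = x, 0-based um grid
})

test_that("nuclei stay inside the field of view at every phase", {
  cfg <- phantom_config(n_slices = 12, n_frames = 30, period_ms = 50,
                        n_nuclei = 18, contraction_amplitude = 0.2, seed = 8)
  fov <- c(cfg$frame_size[2], cfg$frame_size[1], cfg$n_slices) *
    c(cfg$pixel_size_xy, cfg$pixel_size_xy, cfg$step_size_z)
  for (ph in seq(0, 0.95, by = 0.05)) {
    pos <- as.matrix(heart_geometry(cfg, ph)[, c("x", "y", "z")])
    expect_true(all(pos >= 0) && all(pos <= rep(fov, each = nrow(pos))))
  }
})

test_that("bead phantoms honour counts, separations, and analytic FWHM", {
  empty <- generate_beads(0)
  expect_true(all(empty$volume == 0))
  expect_equal(nrow(empty$centers), 0)

  b <- generate_beads(60, seed = 7)
  expect_equal(nrow(b$centers), 60)
  pos_um <- sweep(b$centers, 2, c(0.325, 0.325, 1), "*")
  dmat <- as.matrix(dist(pos_um))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 5 * 2.48)

  # single bead: the axial profile through the centre is an exact Gaussian
  one <- generate_beads(1, volume_shape = c(64L, 64L, 40L), seed = 3)
  ctr <- one$centers[1, ]
  prof <- one$volume[round(ctr["y"]) + 1, round(ctr["x"]) + 1, ]
  half <- min(prof) + (max(prof) - min(prof)) / 2
  above <- range(which(prof >= half))
  # coarse half-max width in voxels ~ FWHM_axial / step = 2.48
  expect_lt(abs(diff(above) - 2.48), 1.5)
  fit <- measure_fwhm(one$volume, ctr, "z", c(0.325, 0.325, 1))
  expect_true(fit$fit_ok)
  expect_equal(fit$fwhm_um, 2.48, tolerance = 0.01)
})

test_that("the adversarial series is constructed with the designed ambiguity", {
  adv <- adversarial_series()
  expect_length(adv$series$movies, 3)
  # the middle movie's pairwise SSD against the first has its global
  # minimum at the false offset, not the true one
  cand <- align_pair(adv$series$movies[[1]], adv$series$movies[[2]],
                     S = 0, L_frames = adv$truth$P)
  expect_equal(cand$D, adv$truth$false_offset)
})
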