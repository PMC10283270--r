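test_that("ssd is a symmetric non-negative form matching a per-pixel loop", {
  a <- array(c(0, 0, 0, 0), c(2, 2, 1))
  b <- array(c(1, 1, 1, 1), c(2, 2, 1))
  expect_identical(ssd(a, a), 0)
  expect_identical(ssd(a, b), 4)
  expect_error(ssd(a, array(0, c(2, 3, 1))), "shape mismatch")

  set.seed(0)
  for (i in 1:10) {
    x <- array(as.numeric(sample.int(4096, 3 * 4 * 4, TRUE) - 1L), c(4, 4, 3))
    y <- array(as.numeric(sample.int(4096, 3 * 4 * 4, TRUE) - 1L), c(4, 4, 3))
    brute <- 0
    for (t in 1:3) for (r in 1:4) for (c in 1:4)
      brute <- brute + (x[r, c, t] - y[r, c, t])^2
    expect_identical(ssd(x, y), brute)
    expect_identical(ssd(x, y), ssd(y, x))
  }
})

test_that("the cycle-length formula reproduces the printed worked example", {
  expect_identical(cycle_length_ms(240, 5), 400)
  expect_error(cycle_length_ms(2, 5))
})

test_that("cycle estimation is exact on periodic movies and agrees with a naive oracle", {
  sim <- grid_phantom()
  mv <- sim$series$movies[[10]]
  est <- estimate_cycle_length(mv, N = 90, E = 5)
  expect_s3_class(est, "cycle_estimate")
  expect_identical(est$best_length_frames, 30L)
  expect_identical(est$ssd_per_candidate[match(30L, est$candidate_lengths)], 0)
  expect_identical(est$L_ms, 150)
  expect_true(est$best_length_frames %in% est$candidate_lengths)
  expect_true(all(est$ssd_per_candidate >= 0))

  # naive reimplementation: explicit back-projection of every frame onto
  # its predecessor one candidate period earlier
  naive <- function(frames, N, E, band = c(0.85, 1.15)) {
    n <- dim(frames)[3]; Lf <- N / 3
    cands <- seq(round(band[1] * Lf), round(band[2] * Lf))
    cands <- cands[cands >= 2 & n >= 2 * cands]
    scores <- vapply(cands, function(P) {
      tot <- 0
      for (t in (P + 1):n) tot <- tot + sum((frames[, , t] - frames[, , t - P])^2)
      tot / (n - P)
    }, 0)
    list(cands = cands, scores = scores,
         best = cands[order(scores, abs(cands - Lf), cands)[1]])
  }
  cfgj <- phantom_config(n_slices = 6, n_frames = 120, period_ms = 150,
                         period_jitter_frac = 0.01, phase_offsets = "random",
                         n_nuclei = 15, seed = 11)
  simj <- generate_series(cfgj)
  mj <- simj$series$movies[[4]]
  estj <- estimate_cycle_length(mj, N = 92, E = 5)
  ref <- naive(mj$frames, 92, 5)
  expect_identical(estj$candidate_lengths, ref$cands)
  expect_equal(estj$ssd_per_candidate, ref$scores)
  expect_identical(estj$best_length_frames, ref$best)
  mean_period <- mean(unlist(simj$truth$periods_ms[[4]])[1:4]) / 5
  expect_lte(abs(estj$best_length_frames - mean_period), 1)
})

test_that("peak-systole counting finds the three-cycle span", {
  sim <- grid_phantom()
  fp <- find_peak_systole(sim$series$movies[[10]])
  expect_gte(length(fp$peaks), 4)
  expect_identical(fp$N, 90L)

  static <- zmovie(array(100, c(8, 8, 20)), meta = acquisition_meta())
  expect_error(find_peak_systole(static), "peaks")
})

test_that("peak counting tolerates 5% intensity noise on the default acquisition", {
  cfg <- phantom_config(seed = 3, n_nuclei = 30, noise_sigma = 150)
  sim <- generate_series(cfg)
  z <- beatsync:::.motion_rich_movie(sim$series)
  fp <- find_peak_systole(sim$series$movies[[z]])
  expect_lte(abs(fp$N - 240L), 2)
})

test_that("pairwise alignment finds content delays exactly (brute-force check)", {
  sim <- grid_phantom()
  P <- sim$P
  ref <- sim$series$movies[[10]]
  expect_identical(align_pair(ref, ref, S = 0, L_frames = P)$D, 0L)

  k <- 17L
  n <- dim(ref$frames)[3]
  shifted <- zmovie(ref$frames[, , (seq_len(n) - 1 + k) %% n + 1],
                    z_index = 1L, meta = ref$meta)
  cand <- align_pair(ref, shifted, S = 0, L_frames = P)
  # brute force: direct SSD at every candidate offset
  clip_len <- cand$clip_length
  brute <- vapply(0:(P - 1), function(D)
    ssd(ref$frames[, , 1:clip_len], shifted$frames[, , (1 + D):(clip_len + D)]), 0)
  expect_identical(which(brute == 0) - 1L, (P - k))
  expect_identical(cand$D, P - k)   # shifted[t] = ref[t + k] => D = P - k
  expect_identical(cand$ssd, 0)
  expect_equal(cand$ssd_per_candidate, brute)
})

test_that("static movie pairs are flagged degenerate with D = 0", {
  static <- zmovie(array(100, c(8, 8, 60)), meta = acquisition_meta())
  cand <- align_pair(static, static, S = 0, L_frames = 10)
  expect_true(cand$degenerate)
  expect_identical(cand$D, 0L)
})

test_that("series alignment recovers ground-truth offsets on a noise-free phantom", {
  sim <- grid_phantom()
  P <- sim$P
  sync <- align_series(sim$series, L_frames = P)
  truth_off <- round(sim$truth$phase_offsets * P)
  expected <- (truth_off[1] - truth_off) %% P
  expect_identical(sync$offsets, as.integer(expected))
  expect_false(any(sync$degenerate))

  # identity series: all offsets zero
  same <- zstack_series(lapply(0:3, function(z) {
    m <- sim$series$movies[[1]]; m$z_index <- z; m
  }))
  expect_identical(align_series(same, L_frames = P)$offsets, rep(0L, 4))
})

test_that("alignment is translation-consistent under content shifts of the reference", {
  sim <- grid_phantom()
  P <- sim$P
  base <- align_series(sim$series, L_frames = P)$offsets
  k <- 7L
  n <- dim(sim$series$movies[[1]]$frames)[3]
  movies <- sim$series$movies
  movies[[1]] <- zmovie(movies[[1]]$frames[, , (seq_len(n) - 1 + k) %% n + 1],
                        z_index = 0L, meta = movies[[1]]$meta)
  shifted <- align_series(zstack_series(movies), L_frames = P)$offsets
  expect_identical(shifted[-1], (base[-1] + k) %% P)
})

test_that("4D assembly copies retained frames verbatim", {
  sim <- grid_phantom()
  P <- sim$P
  # single-slice series: volumes equal the movie's retained window
  single <- zstack_series(list(sim$series$movies[[1]]))
  sync1 <- structure(list(offsets = 0L, cycle_length_frames = P,
                          ref_length_frames = P, retained_cycles = 3L,
                          clip_length_frames = 3L * P, degenerate = FALSE),
                     class = "sync_result")
  v <- assemble_4d(single, sync1)
  expect_length(v$volumes, 3 * P)
  for (t in c(1, 45, 90))
    expect_identical(v$volumes[[t]][, , 1], sim$series$movies[[1]]$frames[, , t])

  # full phantom: assembled volumes equal ground-truth reference volumes
  res <- synchronize(sim$series)
  o0 <- round(sim$truth$phase_offsets[1] * P)
  for (t in c(1, 31, 90)) {
    ref_idx <- (o0 + t - 1) %% P + 1
    expect_identical(res$volume$volumes[[t]], sim$truth$reference_volumes[[ref_idx]])
  }
  expect_length(res$volume$volumes, 3 * P)
  expect_identical(res$volume$time_step, 5)
  # window overflow is an error
  bad <- res$sync
  bad$offsets[2] <- 200L
  expect_error(assemble_4d(sim$series, bad), "window overflow")
})

test_that("synchronize equals its manually composed stages", {
  sim <- grid_phantom()
  res <- synchronize(sim$series)
  est <- estimate_cycle_length(sim$series$movies[[beatsync:::.motion_rich_movie(sim$series)]],
                               N = 90, E = 5)
  sync <- align_series(sim$series, L_frames = est$best_length_frames,
                       per_slice_lengths = res$sync$cycle_length_frames)
  expect_identical(res$sync$offsets, sync$offsets)
  expect_identical(res$volume$volumes,
                   assemble_4d(sim$series, sync)$volumes)
})

test_that("degenerate static series completes with all pairs flagged", {
  meta <- acquisition_meta()
  movies <- lapply(0:3, function(z)
    zmovie(array(500, c(8, 8, 60)), z_index = z, meta = meta))
  series <- zstack_series(movies, meta)
  sync <- align_series(series, L_frames = 10)
  expect_true(all(sync$degenerate))
  expect_identical(sync$offsets, rep(0L, 4))
})
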