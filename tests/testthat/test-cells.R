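test_that("segmentation handles empty volumes and counts well-separated nuclei", {
  empty <- segment_nuclei(array(0, c(12, 12, 8)))
  expect_equal(nrow(empty$table), 0)
  expect_true(all(empty$labels == 0L))

  sim <- easy_track_phantom()
  lv <- sim$labels[[1]]
  K <- sim$config$n_nuclei
  expect_equal(nrow(lv$table), K)
  expect_identical(sort(unique(as.vector(lv$labels[lv$labels > 0]))),
                   seq_len(K))  # consecutive labels
  # every truth nucleus has a centroid within one voxel diagonal
  tp <- sim$truth$trajectories[, , 1]
  cent <- as.matrix(lv$table[, c("x_um", "y_um", "z_um")])
  d <- vapply(seq_len(K), function(i)
    min(sqrt(colSums((t(cent) - tp[i, ])^2))), 0)
  expect_lt(median(d), 1)
  expect_lt(max(d), 2.6)   # boundary-clipped blobs carry the largest bias
})

test_that("watershed splits touching nuclei at the neck", {
  g <- expand.grid(y = 1:40, x = 1:40, z = 1:16)
  dumbbell <- array(
    1000 * exp(-((g$x - 15)^2 + (g$y - 20)^2) / (2 * 2.2^2) - (g$z - 8)^2 / (2 * 2^2)) +
      1000 * exp(-((g$x - 24)^2 + (g$y - 20)^2) / (2 * 2.2^2) - (g$z - 8)^2 / (2 * 2^2)),
    c(40, 40, 16))
  lv <- segment_nuclei(dumbbell, min_seed_separation_um = 4, min_voxels = 10)
  expect_equal(nrow(lv$table), 2)
  expect_setequal(round(lv$table$x_um), c(14, 23))  # 0-based um grid
})

test_that("greedy linking tracks a static phantom without births or jumps", {
  sim <- easy_track_phantom()
  # static: reuse a single timepoint several times
  labs <- sim$labels[c(1, 1, 1, 1)]
  tracks <- link_tracks(labs, max_link_distance_um = 3, dt_ms = 1)
  expect_length(tracks, nrow(sim$labels[[1]]$table))
  for (tr in tracks) {
    expect_false(any(tr$gap))
    expect_equal(max(dist(tr$centroid)), 0)
  }
})

test_that("easy phantoms are tracked perfectly; dropouts leave flagged gaps", {
  sim <- easy_track_phantom()
  tracks <- link_tracks(sim$labels, max_link_distance_um = 3, dt_ms = 9.375)
  expect_length(tracks, sim$config$n_nuclei)  # no spurious births
  sc <- score_tracking(tracks, sim$truth$trajectories, match_radius_um = 2.7)
  expect_identical(sc$accuracy, 1)
  expect_identical(sc$false_positive, 0L)
  expect_identical(sc$false_negative, 0L)

  # delete one nucleus at t = 3: its track must flag a gap there
  labs <- sim$labels
  victim <- labs[[3]]$table$label[5]
  labs[[3]]$labels[labs[[3]]$labels == victim] <- 0L
  labs[[3]]$table <- labs[[3]]$table[labs[[3]]$table$label != victim, ]
  tracks2 <- link_tracks(labs[1:5], max_link_distance_um = 3, dt_ms = 1)
  # the victim's original track (present at t = 0) flags the dropout; the
  # reappearing nucleus starts a fresh track (no gap closing by design)
  orig <- Filter(function(tr) !tr$gap[1], tracks2)
  gaps <- vapply(orig, function(tr) tr$gap[3], TRUE)
  expect_equal(sum(gaps), 1)
  expect_gt(length(tracks2), length(orig))
})

test_that("linkage is symmetric under time reversal", {
  sim <- easy_track_phantom()
  labs <- sim$labels[1:6]
  fwd <- link_tracks(labs, max_link_distance_um = 3, dt_ms = 1)
  rev_tracks <- link_tracks(rev(labs), max_link_distance_um = 3, dt_ms = 1)
  expect_length(rev_tracks, length(fwd))
  fwd_set <- lapply(fwd, function(tr) round(tr$centroid, 9))
  for (tr in rev_tracks) {
    rc <- round(tr$centroid[nrow(tr$centroid):1, ], 9)
    expect_true(any(vapply(fwd_set, identical, TRUE, rc)))
  }
})

test_that("tracking scores behave at the identity, permutation, and empty limits", {
  sim <- easy_track_phantom()
  truth <- sim$truth$trajectories
  T_n <- dim(truth)[3]
  perfect <- lapply(seq_len(dim(truth)[1]), function(i)
    cell_track(i, t(truth[i, , ]), seq_len(T_n) - 1))
  sc <- score_tracking(perfect, truth, match_radius_um = 2)
  expect_identical(sc$accuracy, 1)

  # shuffling centroids across cells destroys the accuracy
  set.seed(4)
  perm <- sample(dim(truth)[1])
  shuffled <- lapply(seq_len(dim(truth)[1]), function(i) {
    cm <- t(truth[i, , ])
    cm[seq(2, T_n, by = 2), ] <- t(truth[perm[i], , ])[seq(2, T_n, by = 2), ]
    cell_track(i, cm, seq_len(T_n) - 1)
  })
  sc_bad <- score_tracking(shuffled, truth, match_radius_um = 2)
  expect_lt(sc_bad$accuracy, 0.5)

  sc_empty <- score_tracking(list(), truth, match_radius_um = 2)
  expect_identical(sc_empty$accuracy, 0)
  expect_identical(sc_empty$false_negative, dim(truth)[1])
})

test_that("region assignment follows the majority of mask membership", {
  masks <- array(0L, c(10, 10, 4))
  masks[, 1:5, ] <- 2L    # atrium occupies x < 5 um
  inside <- cell_track(1, cbind(rep(2, 5), rep(4, 5), rep(1, 5)), 0:4)
  expect_identical(assign_region(inside, masks), "atrium")
  # 40/60 straddle: majority wins
  straddle <- cell_track(2, cbind(c(2, 2, 8, 8, 8), rep(4, 5), rep(1, 5)), 0:4)
  expect_identical(assign_region(straddle, masks), "unassigned") # 60% outside all masks
  masks2 <- masks
  masks2[, 6:10, ] <- 1L
  expect_identical(assign_region(straddle, masks2), "ventricle")

  # phantom tracks get their true region labels
  sim <- easy_track_phantom()
  tracks <- link_tracks(sim$labels, max_link_distance_um = 3, dt_ms = 1)
  pm <- phantom_region_masks(sim$config)
  got <- vapply(tracks, assign_region, "", region_masks = pm)
  # match tracks to truth cells by position at t = 0
  tp <- sim$truth$trajectories[, , 1]
  truth_of <- vapply(tracks, function(tr)
    which.min(colSums((t(tp) - tr$centroid[1, ])^2)), 0L)
  expect_identical(got, sim$truth$regions[truth_of])
})
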