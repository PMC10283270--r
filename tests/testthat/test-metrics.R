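test_that("displacement series honours closed forms and gap rules", {
  t_ms <- 0:9
  static <- cell_track(1, matrix(5, 10, 3), t_ms)
  expect_identical(displacement_series(static), rep(0, 10))

  line <- cell_track(2, cbind(0:9, 0, 0), t_ms)   # 1 um per frame
  expect_equal(displacement_series(line), as.numeric(0:9))

  gappy <- cell_track(3, rbind(c(NA, NA, NA), matrix(0, 9, 3)), t_ms)
  expect_error(displacement_series(gappy), "gap at t = 0")
})

test_that("velocity estimators satisfy closed forms and the O(dt^2) bound", {
  t_ms <- 0:9
  static <- cell_track(1, matrix(5, 10, 3), t_ms)
  expect_identical(velocity_series(static, dt_ms = 1)$speed, rep(0, 10))

  d <- 0.25
  line <- cell_track(2, cbind(d * (0:9), 0, 0), t_ms)
  v <- velocity_series(line, dt_ms = 2)
  expect_equal(v$speed, rep(d / 2, 10))          # um/ms = (um/frame) / (ms/frame)
  vf <- velocity_series(line, dt_ms = 2, method = "forward")
  expect_equal(vf$speed, rep(d / 2, 10))

  # sinusoid: central-difference error bounded by max|x'''| dt^2 / 6
  A <- 3; P_ms <- 40; dt <- 1
  tt <- seq(0, 80, by = dt)
  x <- A * sin(2 * pi * tt / P_ms)
  tr <- cell_track(3, cbind(x, 0, 0), tt)
  v2 <- velocity_series(tr, dt_ms = dt)$speed
  omega <- 2 * pi / P_ms
  truth <- abs(A * omega * cos(omega * tt))
  bound <- A * omega^3 * dt^2 / 6
  interior <- 2:(length(tt) - 1)
  expect_true(all(abs(v2[interior] - truth[interior]) <= bound + 1e-12))

  # time reversal: reversed track gives the reversed speed series
  rev_tr <- cell_track(4, cbind(rev(x), 0, 0), tt)
  v_rev <- velocity_series(rev_tr, dt_ms = dt)$speed
  expect_equal(v_rev[interior], rev(v2)[interior])

  allgap <- cell_track(5, matrix(NA_real_, 5, 3), 0:4)
  expect_error(velocity_series(allgap, 1), "all-gap")
})

test_that("pair distances satisfy identity, 3-4-5, and ground truth", {
  t_ms <- 0:4
  a <- cell_track(1, matrix(1, 5, 3), t_ms)
  expect_identical(pair_distance(a, a)$distance_um, rep(0, 5))
  b <- cell_track(2, matrix(1, 5, 3) + rep(c(3, 4, 0), each = 5), t_ms)
  expect_equal(pair_distance(a, b)$distance_um, rep(5, 5))
  short <- cell_track(3, matrix(0, 4, 3), 0:3)
  expect_error(pair_distance(a, short), "time axes")

  sim <- easy_track_phantom()
  iv <- which(sim$truth$regions == "ventricle")[1]
  ia <- which(sim$truth$regions == "atrium")[1]
  ta <- cell_track(1, t(sim$truth$trajectories[iv, , ]), seq_len(16) - 1)
  tb <- cell_track(2, t(sim$truth$trajectories[ia, , ]), seq_len(16) - 1)
  pd <- pair_distance(ta, tb)
  truth_d <- sqrt(colSums((sim$truth$trajectories[iv, , ] -
                             sim$truth$trajectories[ia, , ])^2))
  expect_equal(pd$distance_um, unname(truth_d))
})

test_that("surface/volume measurements meet their analytic limits", {
  # single-voxel cell: volume is exactly one voxel volume
  single <- array(0, c(9, 9, 9)); single[5, 5, 5] <- 1
  lv1 <- shape_label_volume(single, c(0.5, 0.5, 0.5))
  sv1 <- cell_surface_volume(lv1, 1)
  expect_identical(sv1$volume_um3, 0.125)
  expect_identical(sv1$sav_ratio, sv1$surface_um2 / sv1$volume_um3)

  # sphere r = 10 um at 0.5 um voxels: SA:V within 5% of 3/r
  sph <- voxel_sphere(20)
  svs <- cell_surface_volume(shape_label_volume(sph, rep(0.5, 3)), 1)
  expect_equal(svs$sav_ratio, 0.3, tolerance = 0.05)

  # axis-aligned cube side 10 um: SA:V within 5% of 6/a
  cb <- array(FALSE, c(26, 26, 26)); cb[4:23, 4:23, 4:23] <- TRUE
  svc <- cell_surface_volume(shape_label_volume(cb, rep(0.5, 3)), 1)
  expect_equal(svc$sav_ratio, 0.6, tolerance = 0.05)

  expect_error(cell_surface_volume(lv1, 99), "absent")
})

test_that("among equal-volume shapes the sphere minimises SA:V", {
  sph <- voxel_sphere(10)
  n <- 47; ctr <- 24
  g <- expand.grid(seq_len(n), seq_len(n), seq_len(n))
  # elongated ellipsoid with (nearly) the sphere's voxel volume
  el <- array((g[, 1] - ctr)^2 / 20^2 + (g[, 2] - ctr)^2 / 7.09^2 +
                (g[, 3] - ctr)^2 / 7.09^2 <= 1, c(n, n, n))
  expect_equal(sum(el) / sum(sph), 1, tolerance = 0.02)
  sv_s <- cell_surface_volume(shape_label_volume(sph, rep(1, 3)), 1)
  sv_e <- cell_surface_volume(shape_label_volume(el, rep(1, 3)), 1)
  expect_lt(sv_s$sav_ratio, sv_e$sav_ratio)
})

test_that("mesh export writes one watertight OBJ per cell", {
  sph <- voxel_sphere(6)
  labels <- array(0L, dim(sph) + c(0, 16, 0))
  labels[, 1:19, ][sph] <- 1L
  labels[, 17:35, ][sph] <- 2L
  lv <- structure(list(labels = labels, voxel_size = c(1, 1, 1),
                       table = data.frame(label = 1:2)),
                  class = "label_volume")
  dir <- withr::local_tempdir()
  paths <- export_cell_meshes(lv, dir)
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))
  obj <- readLines(paths[1])
  nv <- sum(startsWith(obj, "v "))
  nf <- sum(startsWith(obj, "f "))
  expect_gt(nv, 0); expect_gt(nf, 0)
  # divergence-theorem mesh volume agrees with the voxel count
  m <- mask_mesh(labels == 1L, c(1, 1, 1))
  expect_equal(mesh_volume(m), sum(labels == 1L), tolerance = 0.05)
})

test_that("regional summaries aggregate correctly and report empty regions", {
  sim <- easy_track_phantom()
  T_n <- dim(sim$truth$trajectories)[3]
  dt <- 9.375
  tracks <- lapply(seq_along(sim$truth$regions), function(i) {
    tr <- cell_track(i, t(sim$truth$trajectories[i, , ]),
                     (seq_len(T_n) - 1) * dt)
    tr$region <- sim$truth$regions[i]
    tr
  })
  tab <- region_summary(tracks, dt_ms = dt)
  expect_identical(tab$region, c("ventricle", "atrium", "AVC"))
  expect_identical(tab$n,
                   unname(vapply(c("ventricle", "atrium", "AVC"),
                                 function(r) sum(sim$truth$regions == r), 0L)))
  # phantom convention: larger atrial amplitude => larger atrial velocity
  expect_gt(tab$avg_velocity_mean[tab$region == "atrium"],
            tab$avg_velocity_mean[tab$region == "ventricle"])
  # single-track region equals that track's own metrics
  one <- region_summary(tracks[1], dt_ms = dt, regions = tracks[[1]]$region)
  expect_equal(one$avg_velocity_mean,
               velocity_series(tracks[[1]], dt)$average_velocity)
  # empty region is reported, not dropped (track 1 sits on the AVC ring)
  empty <- region_summary(tracks[1], dt_ms = dt, regions = "ventricle")
  expect_identical(empty$n, 0L)
})
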