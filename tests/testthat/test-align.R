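# Mini helical reference shared by the alignment tests.
align_fixture <- function() {
  lat <- mini_lattice()
  un <- mini_unit()
  ref <- render_reference(lat, un, 32, 4)
  msk <- soft_mask(32, 4, radius = 15 * 4, soft_edge = 16)
  masked <- density_map(ref$values * msk$values, 4)
  list(lat = lat, ref = ref, masked = masked, prj = projector(masked))
}

make_segment <- function(fx, p, psi_prior = p$psi) {
  img <- project(fx$prj, p)
  structure(list(image = img, micrograph_id = "m", filament_id = "f",
                 arc_position = 0, psi_prior = psi_prior, pose = NULL,
                 ctf = NULL, status = "active"), class = "segment_particle")
}

test_that("a segment generated on the search grid is recovered exactly", {
  fx <- align_fixture()
  p <- pose(40, 90, 10)
  sg <- make_segment(fx, p)
  res <- align_segments(list(sg), fx$masked, angular_step = 10,
                        shift_range = 8, method = "exhaustive",
                        polish_step = 10, mask = FALSE)
  expect_equal(res$poses$rot, 40)
  expect_equal(res$poses$tilt, 90)
  expect_equal(res$poses$psi, 10)
  expect_lt(abs(res$poses$shift_x), 0.5)
  expect_gt(res$scores, 1 - 1e-6)
})

test_that("off-grid noiseless poses are recovered within the stated bounds", {
  fx <- align_fixture()
  set.seed(12)
  truth <- lapply(1:25, function(i)
    pose(runif(1, 0, 360), 90 + runif(1, -10, 10), runif(1, -20, 20),
         shift_x = runif(1, -6, 6), shift_y = runif(1, -6, 6)))
  segs <- lapply(truth, function(p) make_segment(fx, p, psi_prior = 0))
  res <- align_segments(segs, fx$masked, angular_step = 10, psi_width = 25,
                        shift_range = 12, polish_step = 1)
  for (i in seq_along(truth)) {
    err <- angular_distance_helical(res$poses[i, ], truth[[i]], fx$lat$twist)
    expect_lt(err, 10) # angular error <= coarse grid step
    # shift error <= 1 px, modulo the helical shift family
    ks <- -3:3
    sh_err <- min(vapply(ks, function(k) {
      Rk <- pose_matrix(truth[[i]]) %*% c(0, 0, k * fx$lat$rise)
      sqrt(sum((c(res$poses$shift_x[i] - truth[[i]]$shift_x - Rk[1],
                  res$poses$shift_y[i] - truth[[i]]$shift_y - Rk[2]))^2))
    }, numeric(1)))
    if (err < 3) expect_lt(sh_err, 4) # 1 px at 4 A/px
  }
})

test_that("coarse-to-fine equals exhaustive fine-grid search", {
  fx <- align_fixture()
  set.seed(21)
  segs <- lapply(1:10, function(i)
    make_segment(fx, pose(10 * sample(0:35, 1), 90, 5 * sample(-2:2, 1))))
  ex <- align_segments(segs, fx$masked, angular_step = 5, psi_width = 10,
                       tilt_width = 10, shift_range = 8,
                       method = "exhaustive", polish_step = 5)
  cf <- align_segments(segs, fx$masked, angular_step = 5, psi_width = 10,
                       tilt_width = 10, shift_range = 8,
                       method = "coarse_fine", polish_step = 5, bin = 1)
  expect_equal(cf$poses$rot, ex$poses$rot)
  expect_equal(cf$poses$tilt, ex$poses$tilt)
  expect_equal(cf$poses$psi, ex$poses$psi)
  expect_equal(cf$scores, ex$scores, tolerance = 1e-8)
})

test_that("scores never decrease when the grid is refined around the optimum", {
  fx <- align_fixture()
  sg <- make_segment(fx, pose(43.7, 88.2, 7.9))
  steps <- c(20, 10, 5, 2.5)
  scores <- vapply(steps, function(st) {
    align_segments(list(sg), fx$masked, angular_step = st, psi_width = 10,
                   shift_range = 8, polish_step = st, bin = 1)$scores
  }, numeric(1))
  expect_true(all(diff(scores) > -1e-9))
})

test_that("an all-zero reference is rejected", {
  fx <- align_fixture()
  sg <- make_segment(fx, pose(0, 90, 0))
  expect_error(align_segments(list(sg), density_map(array(0, c(32, 32, 32)), 4)),
               "all zero")
})

test_that("consensus from truth poses reproduces reconstruct() bit-for-bit", {
  fx <- align_fixture()
  set.seed(31)
  truth <- do.call(rbind, lapply(1:12, function(i)
    pose(runif(1, 0, 360), 90, runif(1, -10, 10))))
  segs <- lapply(seq_len(12), function(i) make_segment(fx, truth[i, ]))
  imgs <- lapply(segs, `[[`, "image")
  direct <- reconstruct(imgs, truth)
  via <- iterate_consensus(segs, fx$masked, n_iter = 1, initial_poses = truth,
                           score_quantile = 0)
  expect_identical(via$map$values, direct$values)
})

test_that("consensus converges from a filtered bootstrap on rigid data", {
  # The reconstruction of box-filling helical segments carries a
  # forward-model ceiling: segments see the infinite filament while the
  # reference box truncates it, so even exact truth poses reconstruct to
  # ~0.89 correlation against the rendered truth at half-Nyquist here.
  # The test asserts that alignment reaches that ceiling.
  lat <- mini_lattice()
  un <- mini_unit()
  cfg <- simulation_config(pixel_size = 4, micrograph_shape = 384, snr = Inf,
                           ctf = NULL, filaments_per_micrograph = 3, seed = 4)
  ds <- simulate_dataset(lat, un, cfg, n_micrographs = 3, n_units = 50)
  st <- segments_with_truth(ds, box = 48, apix = 4)
  truthm <- render_reference(lat, un, 48, 4)
  init <- lowpass(truthm, 30)
  cons <- iterate_consensus(segs <- st$segments, init, n_iter = 1,
                            angular_step = 10, shift_range = 30,
                            polish_step = 1)
  corr_at <- function(map) {
    lt <- lowpass(truthm, 16)$values # half-Nyquist at 4 A/px
    lc <- lowpass(map, 16)$values
    stats::cor(as.vector(lt), as.vector(lc))
  }
  got <- corr_at(cons$map)
  # the attainable ceiling, measured with the generator's truth poses
  tp <- do.call(rbind, lapply(seq_along(segs), function(i)
    truth_segment_pose(segs[[i]], st$fils[[i]], lat, 384, 4)))
  ceiling_corr <- corr_at(reconstruct(lapply(segs, `[[`, "image"), tp))
  expect_gt(got, 0.85)
  expect_gt(got, 0.95 * ceiling_corr)
  expect_gt(cons$history$mean_score[1], 0.5)
})

test_that("segment count is conserved through score filtering", {
  fx <- align_fixture()
  set.seed(41)
  segs <- lapply(1:10, function(i) make_segment(fx, pose(runif(1, 0, 360), 90, 0)))
  cons <- iterate_consensus(segs, fx$masked, n_iter = 1, angular_step = 15,
                            score_quantile = 0.2)
  expect_length(cons$status, 10)
  expect_equal(sum(cons$status == "active") + sum(cons$status == "rejected"), 10)
  expect_gte(sum(cons$status == "rejected"), 1)
})
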