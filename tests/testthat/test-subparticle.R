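test_that("the demonstration lattice yields 6-8 points of interest in a 20 nm box", {
  v200 <- define_vectors(demo_lattice(), box_a = 200)
  expect_gte(length(v200), 6)
  expect_lte(length(v200), 8)
  v256 <- define_vectors(demo_lattice(), box_a = 256)
  expect_gte(length(v256), 6)
  expect_lte(length(v256), 8)
  for (v in v256) expect_lt(max(abs(v$v)), 128) # inside the box
})

test_that("a single requested region sits at the centre", {
  v <- define_vectors(demo_lattice(), box_a = 200, n_regions = 1)
  expect_length(v, 1)
  expect_equal(v[[1]]$v, c(0, 0, 0))
})

test_that("successive vectors are related by the squared symmetry operator", {
  lat <- demo_lattice()
  vecs <- define_vectors(lat, box_a = 256)
  op <- symmetry_operator(lat, 2)
  for (i in seq_len(length(vecs) - 1)) {
    mapped <- as.vector(op$R %*% vecs[[i]]$v + op$t)
    expect_lt(sqrt(sum((mapped - vecs[[i + 1]]$v)^2)), 0.1)
    expect_equal(vecs[[i + 1]]$rot_offset - vecs[[i]]$rot_offset, 2 * lat$twist)
  }
})

test_that("overlapping regions are rejected naming the offending pair", {
  expect_error(define_vectors(demo_lattice(), box_a = 256, mask_radius = 90),
               "overlap")
})

test_that("region masks satisfy the soft-mask contract", {
  cons <- render_reference(demo_lattice(), demo_asym_unit(), 64, 4)
  vecs <- define_vectors(demo_lattice(), box_a = 256)
  mm <- make_region_masks(cons, vecs, radius = 60, soft_edge = 20, buffer = 20)
  ctr <- which.min(vapply(vecs, function(v) sum(v$v^2), numeric(1)))
  m <- mm$masks[[ctr]]
  expect_true(all(m$values >= 0 & m$values <= 1))
  # value 1 at the region centre, 0 a voxel beyond the radius
  cen_vox <- round(vecs[[ctr]]$v / 4) + 33
  expect_equal(m$values[cen_vox[1], cen_vox[2], cen_vox[3]], 1, tolerance = 1e-6)
  ax <- (seq_len(64) - 33) * 4
  r <- sqrt(array(outer(outer((ax - vecs[[ctr]]$v[1])^2,
                              (ax - vecs[[ctr]]$v[2])^2, `+`),
                        (ax - vecs[[ctr]]$v[3])^2, `+`), dim = c(64, 64, 64)))
  expect_true(all(m$values[r > 60 + 4] == 0))
  # monotone radial profile across the edge
  prof <- helixpsa:::mask_profile(seq(0, 80, by = 1), 60, 20)
  expect_true(all(diff(prof) <= 1e-12))
})

test_that("masks separated by 2r + buffer have exactly zero overlap", {
  cons <- density_map(array(0, c(64, 64, 64)), 4)
  vfar <- list(structure(list(v = c(-70, 0, 0), label = "a", rot_offset = 0),
                         class = "sub_region_vector"),
               structure(list(v = c(70, 0, 0), label = "b", rot_offset = 0),
                         class = "sub_region_vector"))
  mm <- make_region_masks(cons, vfar, radius = 60, soft_edge = 15, buffer = 20)
  expect_equal(max(mm$masks[[1]]$values * mm$masks[[2]]$values), 0)
})

test_that("region masks plus remainder partition unity", {
  cons <- render_reference(demo_lattice(), demo_asym_unit(), 64, 4)
  vecs <- define_vectors(demo_lattice(), box_a = 256)
  mm <- make_region_masks(cons, vecs)
  tot <- Reduce(`+`, lapply(mm$masks, `[[`, "values")) + mm$remainder$values
  expect_lt(max(abs(tot - 1)), 0.02)
})

test_that("buffer below the soft edge warns about duplication risk", {
  cons <- density_map(array(0, c(32, 32, 32)), 4)
  v1 <- list(structure(list(v = c(0, 0, 0), label = "a", rot_offset = 0),
                       class = "sub_region_vector"))
  expect_warning(make_region_masks(cons, v1, radius = 40, soft_edge = 20,
                                   buffer = 10), "duplication")
})

test_that("an all-zero complement subtracts nothing, bit-for-bit", {
  fx <- subtraction_fixture()
  zero <- density_map(array(0, c(64, 64, 64)), 4)
  out <- subtract_signal(fx$seg, fx$cons, zero, p = fx$p)
  expect_identical(out$values, fx$seg$image$values)
})

test_that("subtraction removes >= 90% of out-of-region energy and restores exactly", {
  for (with_ctf in c(FALSE, TRUE)) {
    fx <- subtraction_fixture(with_ctf)
    ctr <- which.min(vapply(fx$vecs, function(v) sum(v$v^2), numeric(1)))
    out <- subtract_signal(fx$seg, fx$cons, fx$masks$complements[[ctr]], p = fx$p)
    # footprint of the kept region in the image
    fp <- project(density_map(fx$masks$masks[[ctr]]$values, 4), fx$p)$values
    outside <- fp < 0.1 * max(fp)
    before <- sum(fx$seg$image$values[outside]^2)
    after <- sum(out$values[outside]^2)
    expect_lt(after / before, 0.1)
    # exact inverse-addability
    expect_equal(out$values + attr(out, "subtracted"), fx$seg$image$values,
                 tolerance = 1e-12)
  }
})

test_that("subtracting from a zero image yields minus the projected complement", {
  fx <- subtraction_fixture(with_ctf = TRUE)
  zseg <- fx$seg
  zseg$image <- image2d(matrix(0, 64, 64), 4)
  ctr <- which.min(vapply(fx$vecs, function(v) sum(v$v^2), numeric(1)))
  out <- subtract_signal(zseg, fx$cons, fx$masks$complements[[ctr]], p = fx$p)
  # oracle: direct projection of the masked volume, CTF-modulated
  masked <- density_map(fx$cons$values * fx$masks$complements[[ctr]]$values, 4)
  S <- helixpsa:::project_slice_ft(projector(masked), fx$p)
  k <- helixpsa:::freq_index_natural(64) / (64 * 4)
  S <- S * ctf_evaluate(zseg$ctf, matrix(k, 64, 64), t(matrix(k, 64, 64)))
  oracle <- Re(helixpsa:::ifft_natural_to_centered(S))
  expect_equal(out$values, -oracle, tolerance = 1e-10)
})

test_that("a missing pose is an error", {
  fx <- subtraction_fixture()
  seg <- fx$seg
  seg$pose <- NULL
  expect_error(subtract_signal(seg, fx$cons, fx$masks$complements[[1]]),
               "pose")
})

test_that("sub-particle re-centring offsets match the rotation-matrix oracle", {
  fx <- subtraction_fixture()
  set.seed(19)
  for (rep in 1:20) {
    p <- pose(runif(1, 0, 360), 90 + runif(1, -15, 15), runif(1, 0, 360),
              shift_x = runif(1, -8, 8), shift_y = runif(1, -8, 8))
    vi <- sample(length(fx$vecs), 1)
    seg <- fx$seg
    sps <- extract_subparticles(list(seg), p, fx$vecs[vi], new_box = 16,
                                subtract = FALSE)
    p_oracle <- (pose_matrix(p) %*% fx$vecs[[vi]]$v)[1:2] +
      c(p$shift_x, p$shift_y)
    if (length(sps)) {
      sp <- sps[[1]]
      recon <- sp$offset_px * 4 + c(sp$pose_prior$shift_x, sp$pose_prior$shift_y)
      expect_lt(max(abs(recon - p_oracle)), 1e-6)
      expect_equal(sp$pose_prior$rot, p$rot + fx$vecs[[vi]]$rot_offset)
      expect_equal(sp$pose_prior$tilt, p$tilt)
      expect_equal(sp$pose_prior$psi, p$psi)
    } else {
      # rejected: oracle confirms the window cannot fit
      c_px <- round(p_oracle / 4)
      fits <- all(abs(c_px) + 8 <= 32)
      expect_false(fits)
    }
  }
})

test_that("extraction count equals the brute-force bounds count", {
  fx <- subtraction_fixture()
  p <- pose(50, 90, 0)
  sps <- extract_subparticles(list(fx$seg), p, fx$vecs, new_box = 32,
                              subtract = FALSE)
  fits <- vapply(fx$vecs, function(vc) {
    c_px <- round(((pose_matrix(p) %*% vc$v)[1:2] + c(p$shift_x, p$shift_y)) / 4)
    all(c_px - 16 + 33 >= 1) && all(c_px + 15 + 33 <= 64)
  }, logical(1))
  expect_length(sps, sum(fits))
  expect_equal(attr(sps, "rejected"), sum(!fits))
  # no two sub-particles of one segment share a vector label
  labs <- vapply(sps, `[[`, character(1), "vector_label")
  expect_equal(anyDuplicated(labs), 0L)
})

test_that("v = 0 gives a centre crop with the parent pose as prior", {
  fx <- subtraction_fixture()
  v0 <- list(structure(list(v = c(0, 0, 0), label = "r0", rot_offset = 0),
                       class = "sub_region_vector"))
  p <- pose(77, 88, 21) # zero shift
  sps <- extract_subparticles(list(fx$seg), p, v0, new_box = 32,
                              subtract = FALSE)
  expect_equal(sps[[1]]$pose_prior, p)
  expect_equal(sps[[1]]$image$values, fx$seg$image$values[17:48, 17:48])
})

test_that("extraction is equivariant under a 90-degree frame rotation", {
  fx <- subtraction_fixture()
  # rotate consensus and vectors by +90 about z; counter-rotate the pose.
  # exact lattice rotation about the centred origin (index 33): the value at
  # (a, b) comes from source (b, 66 - a); the out-of-range edge row is zero
  n <- 64
  rot_vals <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) {
    src <- fx$cons$values[, , k]
    dst <- matrix(0, n, n)
    for (a in 2:n) dst[a, ] <- src[, 66 - a] # dst[a, b] = src[b, 66 - a]
    rot_vals[, , k] <- dst
  }
  cons_rot <- density_map(rot_vals, 4)
  G <- rot_z(90)
  vecs_rot <- lapply(fx$vecs, function(vc) {
    vc$v <- as.vector(G %*% vc$v); vc
  })
  masks_rot <- make_region_masks(cons_rot, vecs_rot)
  p <- fx$p
  R_adj <- pose_matrix(p) %*% t(G)
  eu <- matrix_to_euler(R_adj)
  p_rot <- pose(eu["rot"], eu["tilt"], eu["psi"], p$shift_x, p$shift_y)
  a <- extract_subparticles(list(fx$seg), p, fx$vecs, new_box = 32,
                            consensus = fx$cons, masks = fx$masks)
  b <- extract_subparticles(list(fx$seg), p_rot, vecs_rot, new_box = 32,
                            consensus = cons_rot, masks = masks_rot)
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_gt(stats::cor(as.vector(a[[i]]$image$values),
                         as.vector(b[[i]]$image$values)), 0.99)
  }
})

test_that("the re-centred sub-region reference projects like its sub-particles", {
  fx <- subtraction_fixture()
  ctr <- which.min(vapply(fx$vecs, function(v) sum(v$v^2), numeric(1)))
  subref <- subregion_reference(fx$cons, fx$vecs[[ctr]], 32)
  sps <- extract_subparticles(list(fx$seg), fx$p, fx$vecs[ctr], new_box = 32,
                              consensus = fx$cons,
                              masks = list(masks = fx$masks$masks[ctr],
                                           complements = fx$masks$complements[ctr]))
  pr <- project(subref, sps[[1]]$pose_prior)
  expect_gt(stats::cor(as.vector(pr$values), as.vector(sps[[1]]$image$values)),
            0.9)
})
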