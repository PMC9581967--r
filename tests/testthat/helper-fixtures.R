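# Fixtures shared between module tests and the acceptance tests.

# noiseless segment at a known pose with its consensus, vectors and masks
subtraction_fixture <- function(with_ctf = FALSE) {
  lat <- demo_lattice()
  un <- demo_asym_unit()
  cons <- render_reference(lat, un, 64, 4)
  p <- pose(31, 90, 12, shift_x = 3, shift_y = -2)
  ctf <- if (with_ctf) ctf_params(defocus_u = 12000) else NULL
  prj <- projector(cons)
  S <- helixpsa:::project_slice_ft(prj, p)
  if (with_ctf) {
    k <- helixpsa:::freq_index_natural(64) / (64 * 4)
    S <- S * ctf_evaluate(ctf, matrix(k, 64, 64), t(matrix(k, 64, 64)))
  }
  img <- image2d(Re(helixpsa:::ifft_natural_to_centered(S)), 4)
  seg <- structure(list(image = img, micrograph_id = "m", filament_id = "f",
                        arc_position = 0, psi_prior = 12, pose = p, ctf = ctf,
                        status = "active"), class = "segment_particle")
  vecs <- define_vectors(lat, box_a = 256)
  masks <- make_region_masks(cons, vecs)
  list(lat = lat, cons = cons, seg = seg, p = p, vecs = vecs, masks = masks)
}

make_subparticle <- function(img, prior, fid, ctf = NULL) {
  structure(list(image = img, parent_segment = 1, filament_id = fid,
                 vector_label = "r0", pose_prior = prior, ctf = ctf,
                 offset_px = c(0, 0)), class = "sub_particle")
}

# noiseless sub-particles of a mini helix with known truth poses and
# uniformly jittered priors
refine_fixture <- function(m = 12, jitter = 4, seed = 3, tilt_spread = 10) {
  lat <- mini_lattice()
  ref <- subregion_reference(render_reference(lat, mini_unit(), 64, 4),
                             define_vectors(lat, 256, n_regions = 1)[[1]], 32,
                             radius = 50, soft_edge = 16)
  prj <- projector(ref)
  sps <- withr::with_seed(seed, lapply(seq_len(m), function(i) {
    p <- pose(runif(1, 0, 360), 90 + runif(1, -tilt_spread, tilt_spread),
              runif(1, 0, 360))
    jit <- pose(p$rot + runif(1, -jitter, jitter),
                p$tilt + runif(1, -jitter, jitter),
                p$psi + runif(1, -jitter, jitter))
    sp <- make_subparticle(project(prj, p), jit, sprintf("f%d", i %% 4))
    sp$truth <- p
    sp
  }))
  list(ref = ref, sps = sps)
}

# synthetic zinc-marked coordinate model on the demonstration lattice
synthetic_zinc_model <- function(n_units = 5, scale = 1) {
  lat <- demo_lattice()
  trs <- lattice_poses(lat, n_units)
  atoms <- do.call(rbind, lapply(seq_along(trs), function(k) {
    zn <- trs[[k]]$R %*% c(-3, 2, 1) + trs[[k]]$t # active site lining the groove
    ca <- trs[[k]]$R %*% c(5, 3, 1) + trs[[k]]$t
    data.frame(chain = LETTERS[k], resno = c(600, 156),
               atom = c("ZN", "CA"), element = c("ZN", "C"),
               x = scale * c(zn[1], ca[1]), y = scale * c(zn[2], ca[2]),
               z = scale * c(zn[3], ca[3]))
  }))
  coordinate_model(atoms, "synthetic-helix")
}
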