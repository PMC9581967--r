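#' Pseudo single-particle pipeline on a synthetic filament dataset
#'
#' One call running the full localized-reconstruction procedure the package
#' implements, end to end, on simulated data: simulate micrographs of
#' (possibly flexible) helical filaments; trace and extract overlapping
#' normalized segments; build an asymmetric consensus by projection matching
#' with helical priors, bootstrapped from a low-passed rendering of the
#' ground-truth lattice; assign sub-region vectors to dimer pairs; subtract
#' out-of-region signal and extract re-centred sub-particles; refine them
#' locally as independent single particles; and report gold-standard
#' FSC(0.143) resolutions of both the full-segment consensus and the
#' localized reconstruction.
#'
#' @param lattice,unit filament model ([helical_lattice()],
#'   [asym_unit_model()]); defaults are the meprin-like demonstration model.
#' @param flex `NULL` (rigid control) or a [flex_params()].
#' @param cfg a [simulation_config()].
#' @param n_micrographs,n_units dataset size.
#' @param box segment box (px); `new_box` sub-particle box (px).
#' @param step segment spacing (Angstrom); default box/4 of physical size.
#' @param consensus_iter alignment/reconstruction rounds for the consensus
#'   (the final round polishes at full sampling, earlier rounds binned).
#' @param angular_step,polish_step,shift_range consensus search parameters
#'   (degrees / degrees / Angstrom).
#' @param init_lowpass resolution (Angstrom) of the low-passed truth render
#'   used to bootstrap the consensus (the counterpart of starting from a
#'   tomography average).
#' @param region_radius,region_soft_edge,region_buffer region mask geometry
#'   (Angstrom).
#' @param local_angle_range,local_shift_range,local_fine_step,local_iter
#'   local refinement window and schedule.
#' @param seed master seed for the half-set split.
#' @return list with `consensus` (map, poses, scores, resolution),
#'   `localized` (half maps, poses, resolution), `segments`, `subparticles`,
#'   `vectors`, `resolution_ratio` (consensus/localized resolution, i.e. the
#'   frequency gain of localized refinement), `timing`.
#' @export
run_pseudo_spa <- function(lattice = demo_lattice(), unit = demo_asym_unit(),
                           flex = flex_params(), cfg = simulation_config(),
                           n_micrographs = 4, n_units = 80,
                           box = 64, new_box = 32, step = NULL,
                           consensus_iter = 3, angular_step = 10,
                           polish_step = 0.5, shift_range = 40,
                           init_lowpass = 15,
                           region_radius = 60, region_soft_edge = 20,
                           region_buffer = 20,
                           local_angle_range = 8, local_shift_range = 5,
                           local_fine_step = 0.5, local_iter = 2,
                           seed = 1) {
  t0 <- Sys.time()
  apix <- cfg$pixel_size
  ds <- simulate_dataset(lattice, unit, cfg, n_micrographs = n_micrographs,
                         n_units = n_units, flex = flex)
  segments <- list()
  for (m in seq_along(ds$micrographs)) {
    sim <- ds$micrographs[[m]]
    for (tr in trace_filaments(sim$micrograph, truth = sim$truth)) {
      segments <- c(segments,
                    extract_segments(sim$micrograph, tr, box = box,
                                     step = step, ctf = sim$ctf))
    }
  }
  t_sim <- Sys.time()
  init <- lowpass(render_reference(lattice, unit, box, apix), init_lowpass)
  cons <- iterate_consensus(segments, init, n_iter = consensus_iter,
                            angular_step = angular_step,
                            polish_step = polish_step,
                            shift_range = shift_range)
  keep <- which(cons$status == "active")
  segs_a <- segments[keep]
  poses_a <- cons$poses[keep, , drop = FALSE]
  split <- split_half_sets(segs_a, seed = seed)
  imgs <- lapply(segs_a, `[[`, "image")
  ctfs <- lapply(segs_a, `[[`, "ctf")
  if (all(vapply(ctfs, is.null, logical(1)))) ctfs <- NULL
  cons_a <- reconstruct(imgs[split$a], poses_a[split$a, , drop = FALSE],
                        if (is.null(ctfs)) NULL else ctfs[split$a])
  cons_b <- reconstruct(imgs[split$b], poses_a[split$b, , drop = FALSE],
                        if (is.null(ctfs)) NULL else ctfs[split$b])
  # filament solvent mask: full axial extent, no empty corners
  res_consensus <- gold_standard_resolution(cons_a, cons_b, mask = "cylinder")
  t_cons <- Sys.time()

  vectors <- define_vectors(lattice, box_a = box * apix,
                            mask_radius = region_radius)
  masks <- make_region_masks(cons$map, vectors, radius = region_radius,
                             soft_edge = region_soft_edge,
                             buffer = region_buffer)
  subparticles <- extract_subparticles(segs_a, poses_a, vectors, new_box,
                                       consensus = cons$map, masks = masks)
  central <- which.min(vapply(vectors, function(v) sum(v$v^2), numeric(1)))
  subref <- subregion_reference(cons$map, vectors[[central]], new_box,
                                radius = region_radius,
                                soft_edge = region_soft_edge)
  loc <- local_refine(subparticles, subref,
                      angle_range = local_angle_range,
                      shift_range = local_shift_range,
                      fine_step = local_fine_step, n_iter = local_iter,
                      seed = seed)
  res_localized <- gold_standard_resolution(loc$half_a, loc$half_b)
  t_loc <- Sys.time()
  list(consensus = list(map = cons$map, poses = cons$poses,
                        scores = cons$scores, status = cons$status,
                        half_a = cons_a, half_b = cons_b,
                        resolution = res_consensus),
       localized = list(half_a = loc$half_a, half_b = loc$half_b,
                        poses = loc$poses, scores = loc$scores,
                        resolution = res_localized),
       segments = segments, subparticles = subparticles, vectors = vectors,
       dataset = ds,
       resolution_ratio = res_consensus / res_localized,
       timing = c(simulate = as.numeric(t_sim - t0, units = "secs"),
                  consensus = as.numeric(t_cons - t_sim, units = "secs"),
                  localized = as.numeric(t_loc - t_cons, units = "secs")))
}
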