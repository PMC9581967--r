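#' Gold-standard half-set split
#'
#' Splits sub-particles into two disjoint half-sets by filament id (never by
#' sub-particle), so the half-maps share no parent signal. Deterministic for
#' a given seed.
#'
#' @param subparticles list of `sub_particle`s (anything with a
#'   `filament_id` field).
#' @param seed integer seed.
#' @return list with integer index vectors `a` and `b`.
#' @export
split_half_sets <- function(subparticles, seed = 1) {
  fids <- vapply(subparticles, `[[`, character(1), "filament_id")
  uf <- sort(unique(fids))
  if (length(uf) < 2L)
    stop("split_half_sets: need >= 2 filaments for an independent split; simulate more filaments")
  perm <- withr::with_seed(as.integer(seed), sample(uf))
  half_a <- perm[seq(1, length(perm), by = 2)]
  list(a = which(fids %in% half_a), b = which(!(fids %in% half_a)))
}

#' Local refinement of sub-particles as independent single particles
#'
#' Refines each sub-particle pose on a uniform local grid within
#' `angle_range` degrees of its prior (coarse-to-fine down to `fine_step`)
#' and within `shift_range` Angstrom, then reconstructs the two half-sets
#' independently. With zero ranges the priors are returned unchanged and the
#' half-maps equal plain reconstructions.
#'
#' @param subparticles list of `sub_particle`s.
#' @param reference a [density_map()] sub-region reference (see
#'   [subregion_reference()]).
#' @param angle_range uniform search half-window (degrees).
#' @param shift_range shift half-window (Angstrom).
#' @param fine_step finest angular step (degrees, <= angle_range unless both
#'   are zero).
#' @param coarse_step first-stage angular step (degrees).
#' @param half_split optional result of [split_half_sets()]; computed with
#'   `seed` otherwise.
#' @param seed seed for the half split.
#' @param wiener passed to [reconstruct()].
#' @param mask soft-mask the reference before matching.
#' @param n_iter refinement passes; after each pass the reference is
#'   replaced by the reconstruction from the refined poses (auto-refine
#'   style), which matters when the starting reference comes from a
#'   resolution-limited consensus.
#' @param score_quantile fraction of worst-scoring sub-particles excluded
#'   from the half-map reconstructions (poor-quality particle cleanup, as
#'   for segments).
#' @return list with `poses` (data.frame), `scores`, `half_a`, `half_b`
#'   ([density_map()]s), `split`.
#' @export
local_refine <- function(subparticles, reference, angle_range = 8,
                         shift_range = 5, fine_step = 0.5, coarse_step = 4,
                         half_split = NULL, seed = 1, wiener = NULL,
                         mask = TRUE, n_iter = 1, score_quantile = 0.1) {
  if (!length(subparticles)) stop("local_refine: no sub-particles")
  if (angle_range < 0 || shift_range < 0) stop("local_refine: ranges must be >= 0")
  if (angle_range > 0 && fine_step > angle_range)
    stop("local_refine: fine_step must be <= angle_range")
  apix <- subparticles[[1]]$image$apix
  n <- box_size(subparticles[[1]]$image)
  priors <- do.call(rbind, lapply(subparticles, `[[`, "pose_prior"))
  if (is.null(half_split)) half_split <- split_half_sets(subparticles, seed)
  if (!length(half_split$a) || !length(half_split$b))
    stop("local_refine: a half-set is empty")
  imgs <- lapply(subparticles, `[[`, "image")
  ctfs <- lapply(subparticles, `[[`, "ctf")
  if (all(vapply(ctfs, is.null, logical(1)))) ctfs <- NULL
  if (angle_range == 0 && shift_range == 0) {
    poses <- priors
    scores <- rep(NA_real_, length(subparticles))
  } else {
    msk <- if (mask) soft_mask(n, apix, radius = (n / 2 - 1) * apix,
                               soft_edge = 4 * apix) else NULL
    ref <- reference
    max_shift_px <- max(shift_range / apix, 0.51) # allow sub-pixel fit at 0+
    stages <- local_schedule(angle_range, coarse_step, fine_step)
    IMGs <- lapply(imgs, function(im) image_match_ft(im$values))
    img_norms <- vapply(IMGs, function(IM) sqrt(sum(Mod(IM)^2) / n^2), numeric(1))
    for (it in seq_len(n_iter)) {
      refm <- if (!is.null(msk)) density_map(ref$values * msk$values, apix) else ref
      prj <- projector(refm)
      rows <- vector("list", length(subparticles))
      scores <- numeric(length(subparticles))
      # pass 1 searches the absolute window about the prior; later passes
      # only polish about the already-converged poses
      it_stages <- if (it == 1L || length(stages) == 1L) stages else stages[-1]
      for (i in seq_along(subparticles)) {
        sp <- subparticles[[i]]
        start <- if (it == 1L) sp$pose_prior else poses[i, , drop = FALSE]
        gr <- expand.grid(rot = start$rot + it_stages[[1]]$offsets,
                          tilt = start$tilt + it_stages[[1]]$offsets,
                          psi = start$psi + it_stages[[1]]$offsets)
        best <- match_candidates(IMGs[[i]], img_norms[i], prj, sp$ctf, gr,
                                 max_shift_px)
        for (st in it_stages[-1]) {
          gr <- expand.grid(rot = best$pose$rot + st$offsets,
                            tilt = best$pose$tilt + st$offsets,
                            psi = best$pose$psi + st$offsets)
          res <- match_candidates(IMGs[[i]], img_norms[i], prj, sp$ctf, gr,
                                  max_shift_px)
          if (!is.null(res) && res$score >= best$score) best <- res
        }
        rows[[i]] <- best$pose
        scores[i] <- best$score
      }
      poses <- do.call(rbind, rows)
      if (it < n_iter) {
        # rebuild the reference, filtered at its measured half-map
        # resolution so the next pass does not align against noise
        ha <- reconstruct(imgs[half_split$a], poses[half_split$a, , drop = FALSE],
                          if (is.null(ctfs)) NULL else ctfs[half_split$a], wiener)
        hb <- reconstruct(imgs[half_split$b], poses[half_split$b, , drop = FALSE],
                          if (is.null(ctfs)) NULL else ctfs[half_split$b], wiener)
        res_it <- gold_standard_resolution(ha, hb)
        ref <- reconstruct(imgs, poses, ctfs, wiener)
        if (is.finite(res_it)) ref <- lowpass(ref, res_it)
      }
    }
  }
  keep <- rep(TRUE, length(subparticles))
  if (score_quantile > 0 && !all(is.na(scores))) {
    keep <- scores >= stats::quantile(scores, score_quantile, na.rm = TRUE)
    if (!any(keep[half_split$a]) || !any(keep[half_split$b]))
      keep <- rep(TRUE, length(subparticles))
  }
  rec_half <- function(ix) {
    ix <- ix[keep[ix]]
    reconstruct(imgs[ix], poses[ix, , drop = FALSE],
                if (is.null(ctfs)) NULL else ctfs[ix], wiener)
  }
  list(poses = poses, scores = scores, kept = keep,
       half_a = rec_half(half_split$a), half_b = rec_half(half_split$b),
       split = half_split)
}

# Stage list: offsets vectors for an absolute coarse pass then halving
# passes down to fine_step.
local_schedule <- function(angle_range, coarse_step, fine_step) {
  st1 <- if (angle_range == 0) list(offsets = 0) else
    list(offsets = seq(-angle_range, angle_range,
                       by = min(coarse_step, angle_range)))
  stages <- list(st1)
  s <- min(coarse_step, angle_range) / 2
  while (s >= fine_step && s > 0) {
    stages[[length(stages) + 1L]] <- list(offsets = s * c(-1, 0, 1))
    s <- s / 2
  }
  if (angle_range > 0 && s * 2 > fine_step)
    stages[[length(stages) + 1L]] <- list(offsets = fine_step * c(-1, 0, 1))
  stages
}

#' Gold-standard resolution of two half-maps
#'
#' FSC between independently refined half-maps under a soft mask, reported
#' at the 0.143 crossing.
#'
#' @param half_a,half_b [density_map()]s on the same grid.
#' @param mask `NULL`, a [density_map()], `"sphere"` for a default soft
#'   spherical mask, or `"cylinder"` for a soft cylindrical mask (axis = z)
#'   of radius `mask_radius` — the natural solvent mask for a filament box,
#'   spanning the full axis without the empty corners.
#' @param mask_radius radius (Angstrom) for the named masks; default fills
#'   the box.
#' @param threshold FSC threshold (0.143 gold-standard default).
#' @return resolution in Angstrom.
#' @export
gold_standard_resolution <- function(half_a, half_b, mask = "sphere",
                                     mask_radius = NULL, threshold = 0.143) {
  if (identical(mask, "sphere") || identical(mask, "cylinder")) {
    n <- box_size(half_a)
    if (is.null(mask_radius)) mask_radius <- (n / 2 - 1) * half_a$apix
    mask <- soft_mask(n, half_a$apix, radius = mask_radius,
                      soft_edge = 4 * half_a$apix, shape = mask)
  }
  resolution_at(fsc(half_a, half_b, mask), threshold)
}
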