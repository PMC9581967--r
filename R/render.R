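#' Render a pseudo-atom phantom volume
#'
#' Sums isotropic 3D Gaussians `w * exp(-|r - p|^2 / (2 sigma^2))` over all
#' pseudo-atoms of all placed units. Linear in poses and weights. Pseudo-atom
#' centres falling outside the grid have their contribution clipped with a
#' warning.
#'
#' @param unit an [asym_unit_model()].
#' @param transforms list of `list(R, t)` rigid transforms (see
#'   [lattice_poses()]), mapping unit-frame Angstrom coordinates into the
#'   centred physical frame of the grid.
#' @param n box edge (voxels, even).
#' @param apix pixel size (Angstrom).
#' @param cutoff_sigmas Gaussians are evaluated within this many sigmas.
#' @return a [density_map()].
#' @export
render_volume <- function(unit, transforms, n, apix, cutoff_sigmas = 4) {
  stopifnot(inherits(unit, "asym_unit_model"))
  if (apix <= 0) stop("render_volume: apix must be > 0")
  vol <- array(0, dim = c(n, n, n))
  at <- unit$pseudo_atoms
  ax <- axis_coords(n, apix)
  half <- n * apix / 2
  clipped <- 0L
  for (tr in transforms) {
    pos <- tr$R %*% t(as.matrix(at[, c("x", "y", "z")])) + tr$t
    for (a in seq_len(nrow(at))) {
      p <- pos[, a]
      sg <- at$width[a]
      if (any(p < -half + 1 | p > half - 1)) clipped <- clipped + 1L
      rng <- lapply(p, function(pc) {
        which(ax >= pc - cutoff_sigmas * sg & ax <= pc + cutoff_sigmas * sg)
      })
      if (any(lengths(rng) == 0L)) next
      gx <- exp(-(ax[rng[[1]]] - p[1])^2 / (2 * sg^2))
      gy <- exp(-(ax[rng[[2]]] - p[2])^2 / (2 * sg^2))
      gz <- exp(-(ax[rng[[3]]] - p[3])^2 / (2 * sg^2))
      vol[rng[[1]], rng[[2]], rng[[3]]] <-
        vol[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] +
        at$weight[a] * outer(outer(gx, gy), gz)
    }
  }
  if (clipped > 0L)
    warning(sprintf("render_volume: %d pseudo-atom placement(s) clipped at the grid edge", clipped))
  density_map(vol, apix)
}

#' Render the canonical reference segment of a lattice
#'
#' The ideal (rigid) helical segment used as ground truth and as the frame
#' for sub-region vectors: units at azimuth `k * twist`, axial `k * rise`,
#' re-centred so the axis passes through the box origin and the central unit
#' sits at z = 0 azimuth 0.
#'
#' @param lattice a [helical_lattice()].
#' @param unit an [asym_unit_model()].
#' @param n box edge (voxels).
#' @param apix pixel size (Angstrom).
#' @return a [density_map()].
#' @export
render_reference <- function(lattice, unit, n, apix) {
  n_fit <- ceiling(n * apix / lattice$rise) + 4L
  k0 <- n_fit %/% 2L
  trs <- lattice_poses(lattice, n_fit)
  # shift so that unit k0 sits at z = 0 with azimuth 0
  op <- symmetry_operator(lattice, -k0)
  trs <- lapply(trs, function(tr) compose_transform(op, tr))
  suppressWarnings(render_volume(unit, trs, n, apix))
}
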