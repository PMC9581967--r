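#' Sub-region vectors on the consensus lattice
#'
#' Assigns one vector per non-overlapping dimer-pair region: pair p covers
#' lattice units (2p, 2p+1) relative to the box-centre unit, and its vector
#' points from the consensus box centre to the midpoint of the two lattice
#' points. Successive vectors are related by the squared helical symmetry
#' operator `(Rz(2 twist), 2 rise)`. With the demonstration lattice in a
#' 20 nm box this yields between 6 and 8 points of interest.
#'
#' @param lattice a [helical_lattice()] describing the consensus.
#' @param box_a physical consensus box size (Angstrom).
#' @param n_regions optional: keep only this many most-central regions.
#'   `n_regions = 1` returns the single centred region (zero vector).
#' @param margin keep regions whose unit axial positions are within
#'   `box_a/2 - margin` (Angstrom).
#' @param mask_radius region mask radius (Angstrom) used to check that the
#'   requested regions cannot overlap; adjacent centres closer than
#'   `2 * mask_radius` raise an error naming the offending pair.
#' @return list of `sub_region_vector` objects: `list(v, label,
#'   rot_offset)`; `rot_offset` (degrees) maps poses against the central
#'   region's re-centred reference.
#' @export
define_vectors <- function(lattice, box_a, n_regions = NULL, margin = 10,
                           mask_radius = 60) {
  stopifnot(inherits(lattice, "helical_lattice"))
  if (!is.null(n_regions) && n_regions == 1) {
    return(list(structure(list(v = c(0, 0, 0), label = "r0", rot_offset = 0),
                          class = "sub_region_vector")))
  }
  half <- box_a / 2 - margin
  p_max <- floor(half / lattice$rise) # generous bound; filtered below
  ps <- seq.int(-p_max, p_max)
  keep <- vapply(ps, function(p) {
    z1 <- (2 * p) * lattice$rise
    z2 <- (2 * p + 1) * lattice$rise
    abs(z1) <= half && abs(z2) <= half
  }, logical(1))
  ps <- ps[keep]
  if (!length(ps)) stop("define_vectors: no region fits the box")
  if (!is.null(n_regions)) {
    if (n_regions > length(ps))
      stop("define_vectors: only ", length(ps), " non-overlapping regions fit")
    ps <- ps[order(abs(ps + 0.25))][seq_len(n_regions)]
    ps <- sort(ps)
  }
  lat_point <- function(j) {
    a <- deg2rad(j * lattice$twist)
    c(lattice$radius * cos(a), lattice$radius * sin(a), j * lattice$rise)
  }
  vecs <- lapply(ps, function(p) {
    v <- (lat_point(2 * p) + lat_point(2 * p + 1)) / 2
    structure(list(v = v, label = sprintf("r%+d", p),
                   rot_offset = 2 * p * lattice$twist),
              class = "sub_region_vector")
  })
  # overlap check at the given mask radius
  for (i in seq_along(vecs)) {
    for (j in seq_len(i - 1L)) {
      d <- sqrt(sum((vecs[[i]]$v - vecs[[j]]$v)^2))
      if (d < 2 * mask_radius)
        stop(sprintf(
          "define_vectors: regions %s and %s overlap (centres %.1f A apart < 2 x mask radius %.1f A)",
          vecs[[j]]$label, vecs[[i]]$label, d, mask_radius))
    }
  }
  vecs
}

#' Soft region masks and their complements
#'
#' One soft spherical mask per sub-region vector (value 1 inside
#' `radius - soft_edge`, cosine ramp, exactly 0 at and beyond `radius`), the
#' per-region complement `1 - mask` used for partial signal subtraction, and
#' the remainder `clamp(1 - sum(masks))`. Adjacent masks whose centres are at
#' least `2 * radius + buffer` apart have exactly zero pointwise product; a
#' buffer smaller than the soft edge risks duplicated signal and triggers a
#' warning.
#'
#' @param consensus a [density_map()] defining the grid.
#' @param vectors list of `sub_region_vector`s.
#' @param radius mask radius (Angstrom).
#' @param soft_edge cosine edge width inside `radius` (Angstrom).
#' @param buffer intended spacing between region surfaces (Angstrom);
#'   checked, not applied.
#' @return list with `masks`, `complements` (lists of [density_map()]s) and
#'   `remainder`.
#' @export
make_region_masks <- function(consensus, vectors, radius = 60,
                              soft_edge = 20, buffer = soft_edge) {
  stopifnot(inherits(consensus, "density_map"))
  if (radius <= 0 || soft_edge <= 0 || buffer <= 0)
    stop("make_region_masks: radius, soft_edge and buffer must be > 0")
  if (buffer < soft_edge)
    warning("make_region_masks: buffer < soft_edge risks particle duplication")
  n <- box_size(consensus)
  apix <- consensus$apix
  masks <- lapply(vectors, function(vc)
    soft_mask(n, apix, radius = radius, soft_edge = soft_edge, centre = vc$v))
  complements <- lapply(masks, function(m)
    density_map(1 - m$values, apix))
  tot <- Reduce(`+`, lapply(masks, `[[`, "values"))
  remainder <- density_map(pmin(pmax(1 - tot, 0), 1), apix)
  list(masks = masks, complements = complements, remainder = remainder)
}

#' Partial signal subtraction
#'
#' Removes from a segment image the CTF-modulated projection of the
#' consensus density outside the region of interest:
#' `I' = I - CTF (*) project(consensus x complement, pose)`. The subtracted
#' term is stored in the attribute `"subtracted"`, so adding it back
#' restores the input exactly.
#'
#' @param segment a `segment_particle` (supplies the image and CTF).
#' @param consensus a [density_map()], or a [projector()] of the
#'   complement-masked consensus (preferred when looping over segments).
#' @param complement_mask a [density_map()] with values in \[0, 1\]; ignored
#'   when `consensus` is already a projector.
#' @param p the segment's refined pose (one-row data.frame); required.
#' @return an [image2d()] with attribute `"subtracted"`.
#' @export
subtract_signal <- function(segment, consensus, complement_mask = NULL, p = segment$pose) {
  if (is.null(p)) stop("subtract_signal: segment has no refined pose")
  check_poses(p, 1L)
  prj <- if (inherits(consensus, "projector")) consensus else {
    v <- if (is.null(complement_mask)) consensus$values else
      consensus$values * complement_mask$values
    projector(density_map(v, consensus$apix))
  }
  S <- project_slice_ft(prj, p)
  if (!is.null(segment$ctf)) {
    n <- prj$n
    k <- freq_index_natural(n) / (n * prj$apix)
    S <- S * ctf_evaluate(segment$ctf, matrix(k, n, n), t(matrix(k, n, n)))
  }
  sub <- Re(ifft_natural_to_centered(S))
  out <- image2d(segment$image$values - sub, segment$image$apix)
  attr(out, "subtracted") <- sub
  out
}

#' Localized sub-particle extraction
#'
#' For every (segment, vector) pair: subtract the signal of everything
#' outside the region (unless `subtract = FALSE`), locate the region centre
#' in the image at `p2d = (R v)_xy + shift` (R the segment pose rotation),
#' and re-window a `new_box` image centred there. The pose prior keeps the
#' parent angles with the vector's `rot_offset` added to `rot` (mapping all
#' regions onto the central re-centred two-dimer reference) and carries the
#' sub-pixel re-centring residual as its shift. Windows that do not fit
#' inside the parent box are rejected and recorded.
#'
#' @param segments list of `segment_particle`s.
#' @param pose_table data.frame of refined segment poses (one row each).
#' @param vectors list of `sub_region_vector`s.
#' @param new_box sub-particle box (px, even, < segment box).
#' @param consensus a [density_map()]; required when `subtract = TRUE`.
#' @param masks result of [make_region_masks()]; required when
#'   `subtract = TRUE`.
#' @param subtract perform partial signal subtraction (default TRUE).
#' @return list of `sub_particle` objects: `list(image, parent_segment,
#'   filament_id, vector_label, pose_prior, ctf, offset_px)`; the attribute
#'   `"rejected"` counts out-of-bounds windows.
#' @export
extract_subparticles <- function(segments, pose_table, vectors, new_box,
                                 consensus = NULL, masks = NULL,
                                 subtract = TRUE) {
  if (!length(segments)) return(list())
  check_poses(pose_table, length(segments))
  b <- box_size(segments[[1]]$image)
  if (new_box >= b) stop("extract_subparticles: new_box must be < segment box")
  if (new_box %% 2L != 0L) stop("extract_subparticles: new_box must be even")
  apix <- segments[[1]]$image$apix
  if (subtract && (is.null(consensus) || is.null(masks)))
    stop("extract_subparticles: subtraction needs `consensus` and `masks`")
  if (subtract && length(masks$complements) != length(vectors))
    stop("extract_subparticles: one complement mask per vector required")
  prjs <- if (subtract) lapply(masks$complements, function(cm)
    projector(density_map(consensus$values * cm$values, consensus$apix))) else NULL
  out <- list()
  rejected <- 0L
  cen <- b %/% 2L + 1L
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    p <- pose_table[i, , drop = FALSE]
    R <- pose_matrix(p)
    for (vi in seq_along(vectors)) {
      vc <- vectors[[vi]]
      img <- if (subtract) subtract_signal(sg, prjs[[vi]], p = p) else sg$image
      p2d <- (R %*% vc$v)[1:2] + c(p$shift_x, p$shift_y)
      c_px <- round(p2d / apix)
      resid_a <- p2d - c_px * apix
      ix <- cen + c_px[1] - new_box %/% 2L + seq_len(new_box) - 1L
      iy <- cen + c_px[2] - new_box %/% 2L + seq_len(new_box) - 1L
      if (ix[1] < 1L || iy[1] < 1L || ix[new_box] > b || iy[new_box] > b) {
        rejected <- rejected + 1L
        next
      }
      out[[length(out) + 1L]] <- structure(
        list(image = image2d(img$values[ix, iy], apix),
             parent_segment = i,
             filament_id = sg$filament_id,
             vector_label = vc$label,
             pose_prior = pose(p$rot + vc$rot_offset, p$tilt, p$psi,
                               resid_a[1], resid_a[2]),
             ctf = sg$ctf,
             offset_px = c_px),
        class = "sub_particle")
    }
  }
  if (!length(out)) warning("extract_subparticles: all sub-particles out of bounds")
  attr(out, "rejected") <- rejected
  out
}

#' Re-centred sub-region reference
#'
#' Masks the consensus with the central region mask, translates the region
#' centre to the box origin (Fourier phase shift, sub-voxel exact) and crops
#' to the sub-particle box — the reference against which sub-particles are
#' locally refined.
#'
#' @param consensus a [density_map()].
#' @param vector the `sub_region_vector` of the (usually central) region.
#' @param new_box sub-particle box (px).
#' @param radius,soft_edge mask geometry (Angstrom), as in
#'   [make_region_masks()].
#' @return a [density_map()] of edge `new_box`.
#' @export
subregion_reference <- function(consensus, vector, new_box, radius = 60,
                                soft_edge = 20) {
  n <- box_size(consensus)
  apix <- consensus$apix
  m <- soft_mask(n, apix, radius = radius, soft_edge = soft_edge,
                 centre = vector$v)
  masked <- consensus$values * m$values
  shifted <- shift_map_values(masked, -vector$v / apix)
  off <- (n - new_box) %/% 2L
  density_map(shifted[off + seq_len(new_box), off + seq_len(new_box),
                      off + seq_len(new_box)], apix)
}

# Translate a 3D array by dv voxels (content moves +dv), Fourier phase ramp.
shift_map_values <- function(values, dv) {
  n <- dim(values)[1]
  f <- freq_index(n) / n
  ph <- exp(-2i * pi * outer(outer(f * dv[1], f * dv[2], `+`), f * dv[3], `+`))
  Re(ifft_centered(fft_centered(values) * ph))
}
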