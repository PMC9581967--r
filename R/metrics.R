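#' Coordinate models
#'
#' A light atom-table representation: one row per atom with chain, residue
#' number, atom name, element, coordinates (Angstrom), occupancy and
#' B-factor. `read_coordinate_model` wraps `bio3d::read.pdb`.
#'
#' @param atoms data.frame with columns `chain, resno, atom, element,
#'   x, y, z` (optionally `occ`, `b`).
#' @param source_id identifier.
#' @return an object of class `coordinate_model`.
#' @export
coordinate_model <- function(atoms, source_id = "model") {
  need <- c("chain", "resno", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("coordinate_model: atoms needs columns ", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinate_model: non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("coordinate_model: duplicated (chain, residue, atom) entries")
  structure(list(atoms = atoms, source_id = source_id),
            class = "coordinate_model")
}

#' @rdname coordinate_model
#' @param path PDB file path.
#' @export
read_coordinate_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  el <- a$elesy
  el[is.na(el) | el == ""] <- substr(trimws(a$elety[is.na(el) | el == ""]), 1, 1)
  coordinate_model(data.frame(chain = a$chain, resno = a$resno,
                              atom = trimws(a$elety), element = trimws(el),
                              x = a$x, y = a$y, z = a$z,
                              occ = a$o, b = a$b),
                   source_id = basename(path))
}

#' Helix envelope geometry from a density map
#'
#' Fits the helical axis (principal axis of above-threshold voxels, refined
#' by per-slab centroiding), builds the radial occupancy profile of the
#' thresholded density about that axis, and reports the outer diameter
#' (2 x largest radius still occupied) and the lumen diameter (2 x largest
#' radius of the contiguous empty core).
#'
#' @param map a [density_map()] containing a filament along (roughly) one
#'   axis.
#' @param threshold density threshold, or `"auto"` (mean + 2 sd of positive
#'   voxels).
#' @param occupancy_cut fraction of an annulus that must be filled for a
#'   radius to count as occupied.
#' @return a `geometry_report` list: `outer_diameter`, `lumen_diameter`
#'   (Angstrom), `axis` (unit 3-vector), `axis_fit_residual` (Angstrom),
#'   `profile` (data.frame radius/occupancy).
#' @export
helix_geometry <- function(map, threshold = "auto", occupancy_cut = 0.01) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  if (identical(threshold, "auto")) {
    pos <- v[v > 0]
    threshold <- mean(pos) + 2 * stats::sd(pos)
  }
  if (threshold <= 0) stop("helix_geometry: threshold must be positive")
  sel <- which(v > threshold)
  if (!length(sel)) stop("helix_geometry: no voxels above threshold")
  n <- box_size(map)
  apix <- map$apix
  idx <- arrayInd(sel, dim(v))
  xyz <- (idx - (n / 2 + 1)) * apix
  w <- v[sel]
  ctr <- colSums(xyz * w) / sum(w)
  xc <- sweep(xyz, 2, ctr)
  pc <- eigen(crossprod(xc * sqrt(w)) / sum(w), symmetric = TRUE)
  axis <- pc$vectors[, 1]
  # refine direction by slab centroiding: slabs along the axis, re-fit line
  t_par <- xc %*% axis
  slab <- round(t_par / (4 * apix))
  cent <- t(vapply(split(seq_len(nrow(xc)), slab), function(ix) {
    colSums(xc[ix, , drop = FALSE] * w[ix]) / sum(w[ix])
  }, numeric(3)))
  if (nrow(cent) >= 3) {
    cc <- sweep(cent, 2, colMeans(cent))
    axis <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  }
  # axis position: Kasa circle fit of the voxel cloud projected onto the
  # plane perpendicular to the axis (the centroid of a partial-turn helix
  # segment lies off-axis, a circle fit does not)
  u1 <- if (abs(axis[1]) < 0.9) cross3(axis, c(1, 0, 0)) else cross3(axis, c(0, 1, 0))
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- cross3(axis, u1)
  xy <- xc %*% cbind(u1, u2)
  ks <- stats::lsfit(2 * xy, rowSums(xy^2), wt = w, intercept = TRUE)
  centre2 <- ks$coefficients[2:3]
  r_perp <- sqrt((xy[, 1] - centre2[1])^2 + (xy[, 2] - centre2[2])^2)
  # axis straightness: spread of per-quarter circle centres
  t_par <- xc %*% axis
  quarters <- cut(as.vector(t_par), 4, labels = FALSE)
  qc <- vapply(1:4, function(q) {
    ix <- which(quarters == q)
    if (length(ix) < 20) return(c(NA_real_, NA_real_))
    kq <- stats::lsfit(2 * xy[ix, , drop = FALSE], rowSums(xy[ix, , drop = FALSE]^2),
                       wt = w[ix], intercept = TRUE)
    kq$coefficients[2:3]
  }, numeric(2))
  resid <- sqrt(mean(colSums((qc - centre2)^2), na.rm = TRUE))
  # radial occupancy: voxel count per 1-voxel annulus / expected full count
  len <- diff(range(t_par)) + apix
  rb <- floor(r_perp / apix)
  counts <- tabulate(rb + 1L, nbins = max(rb) + 1L)
  radii <- (seq_along(counts) - 0.5) * apix
  expected <- 2 * pi * radii * apix * len / apix^3
  occ <- counts / pmax(expected, 1)
  occupied <- occ >= occupancy_cut
  if (!any(occupied)) stop("helix_geometry: nothing occupied at this cut")
  outer_r <- radii[max(which(occupied))] + 0.5 * apix
  first_occ <- min(which(occupied))
  lumen_r <- if (first_occ > 1) radii[first_occ - 1L] + 0.5 * apix else 0
  structure(list(outer_diameter = 2 * outer_r, lumen_diameter = 2 * lumen_r,
                 axis = axis, axis_fit_residual = resid,
                 profile = data.frame(radius = radii, occupancy = occ)),
            class = "geometry_report")
}

#' Groove width and repeating-site spacing
#'
#' For a helical lattice: the groove is the axial gap between successive
#' turns, `pitch - envelope_extent`, with `pitch = rise * 360 / |twist|`;
#' the site spacing is the Euclidean distance between equivalent landmark
#' points (e.g. catalytic zincs) of adjacent repeating units,
#' `sqrt((2 r sin(twist/2))^2 + rise^2)` at landmark radius `r`.
#'
#' For a [coordinate_model()]: the spacing is the median over selected
#' landmark atoms of the distance to their nearest fellow landmark — for a
#' helical arrangement each site's nearest neighbour is the adjacent
#' repeating unit, with no axis fit required. Groove requires the lattice
#' parameterization and is `NA` otherwise.
#'
#' @param x a [helical_lattice()] or [coordinate_model()].
#' @param envelope_extent axial extent of one turn's density envelope
#'   (Angstrom; lattice input).
#' @param site_radius landmark radius (Angstrom); defaults to the lattice
#'   radius.
#' @param selector for coordinate models: a function(atoms) returning a row
#'   filter, or a list like `list(element = "ZN")` /
#'   `list(atom = "CA", resno = 156)`; an empty selection raises an error
#'   listing available elements.
#' @return list with `groove` and `site_spacing` (Angstrom).
#' @export
groove_and_spacing <- function(x, envelope_extent = NULL, site_radius = NULL,
                               selector = list(element = "ZN")) {
  if (inherits(x, "helical_lattice")) {
    if (is.null(envelope_extent))
      stop("groove_and_spacing: envelope_extent required for a lattice")
    pitch <- x$rise * 360 / abs(x$twist)
    r <- if (is.null(site_radius)) x$radius else site_radius
    spacing <- sqrt((2 * r * sin(abs(deg2rad(x$twist)) / 2))^2 + x$rise^2)
    return(list(groove = pitch - envelope_extent, site_spacing = spacing,
                pitch = pitch))
  }
  stopifnot(inherits(x, "coordinate_model"))
  at <- x$atoms
  keep <- rep(TRUE, nrow(at))
  if (is.function(selector)) {
    keep <- selector(at)
  } else {
    for (nm in names(selector))
      keep <- keep & (toupper(trimws(at[[nm]])) %in% toupper(selector[[nm]]))
  }
  sites <- at[keep, , drop = FALSE]
  if (nrow(sites) < 2L)
    stop("groove_and_spacing: selector matched ", nrow(sites),
         " atom(s); need >= 2. Available elements: ",
         paste(sort(unique(at$element)), collapse = ", "))
  p <- as.matrix(sites[, c("x", "y", "z")])
  nn <- vapply(seq_len(nrow(p)), function(i) {
    min(sqrt(rowSums(sweep(p[-i, , drop = FALSE], 2, p[i, ])^2)))
  }, numeric(1))
  list(groove = NA_real_, site_spacing = stats::median(nn))
}

#' Groove width measured from a helical density map
#'
#' Projects above-threshold voxels of the helical wall onto the unwrapped
#' helical phase `zeta = z - (rise/twist) * azimuth` (mod pitch), where the
#' density of an ideal helix concentrates in a single band per turn. The
#' groove is the empty part of the period: `pitch - band_extent`.
#'
#' @param map a [density_map()] with the filament axis along z (as rendered
#'   by [render_reference()]).
#' @param lattice the [helical_lattice()] supplying rise and twist.
#' @param threshold density threshold or `"auto"`: the mean of the positive
#'   voxels, a display-level contour — the groove is a surface feature and
#'   its width is quoted at the contour one would render.
#' @param radial_band radii (Angstrom, length 2) of the wall shell used;
#'   default `lattice$radius + c(-25, 25)`.
#' @param occupied_frac a phase bin counts as occupied if it holds at least
#'   this fraction of the maximum bin count.
#' @return list with `groove`, `envelope_extent`, `pitch` (Angstrom).
#' @export
helix_groove <- function(map, lattice, threshold = "auto",
                         radial_band = lattice$radius + c(-25, 25),
                         occupied_frac = 0.05) {
  stopifnot(inherits(map, "density_map"), inherits(lattice, "helical_lattice"))
  v <- map$values
  if (identical(threshold, "auto")) {
    threshold <- mean(v[v > 0])
  }
  sel <- which(v > threshold)
  if (!length(sel)) stop("helix_groove: no voxels above threshold")
  n <- box_size(map)
  apix <- map$apix
  xyz <- (arrayInd(sel, dim(v)) - (n / 2 + 1)) * apix
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  keep <- r >= radial_band[1] & r <= radial_band[2]
  if (!any(keep)) stop("helix_groove: no wall voxels in the radial band")
  xyz <- xyz[keep, , drop = FALSE]
  phi <- atan2(xyz[, 2], xyz[, 1]) * 180 / pi
  pitch <- lattice$rise * 360 / abs(lattice$twist)
  zeta <- (xyz[, 3] - (lattice$rise / lattice$twist) * phi) %% pitch
  nb <- max(8L, round(pitch / apix))
  bins <- floor(zeta / pitch * nb) + 1L
  counts <- tabulate(bins, nbins = nb)
  occupied <- counts >= occupied_frac * max(counts)
  extent <- sum(occupied) * pitch / nb
  list(groove = pitch - extent, envelope_extent = extent, pitch = pitch)
}

# Van der Waals radii (Angstrom) for SASA; standard Bondi-style values.
vdw_radii <- stats::setNames(
  c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.90, 1.39, 1.47, 1.75, 1.85,
    1.98, 1.73, 2.31, 1.63, 2.27, 2.75, 1.61, 1.40),
  c("H", "C", "N", "O", "S", "P", "SE", "ZN", "F", "CL", "BR",
    "I", "MG", "CA", "FE", "NA", "K", "MN", "CU"))

# Golden-spiral quasi-uniform points on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley SASA per atom (A^2) for an atom table subset.
sasa_atoms <- function(xyz, elements, probe = 1.4, n_points = 960) {
  el <- toupper(elements)
  unknown <- setdiff(unique(el), names(vdw_radii))
  if (length(unknown))
    stop("buried_interface_area: no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- vdw_radii[el] + probe
  n <- nrow(xyz)
  sp <- sphere_points(n_points)
  out <- numeric(n)
  # neighbour lists by cutoff
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    pts <- sweep(sp * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj >= r[j]^2
    }
    out[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  out
}

#' Buried interface area between two chain groups
#'
#' Solvent-accessible surface area lost on complex formation, reported under
#' the halved convention used by interface servers:
#' `(SASA_A + SASA_B - SASA_AB) / 2`. Shrake-Rupley quadrature with probe
#' 1.4 Angstrom and 960 sphere points per atom by default; exactly zero for
#' non-contacting groups and symmetric in the two groups.
#'
#' @param model a [coordinate_model()].
#' @param group_a,group_b character vectors of chain ids (disjoint,
#'   non-empty).
#' @param probe probe radius (Angstrom).
#' @param points_per_atom quadrature points per atom (>= 100).
#' @return buried area in Angstrom^2.
#' @export
buried_interface_area <- function(model, group_a, group_b, probe = 1.4,
                                  points_per_atom = 960) {
  stopifnot(inherits(model, "coordinate_model"))
  if (length(intersect(group_a, group_b)))
    stop("buried_interface_area: groups must be disjoint")
  at <- model$atoms
  ia <- at$chain %in% group_a
  ib <- at$chain %in% group_b
  if (!any(ia) || !any(ib))
    stop("buried_interface_area: empty chain group")
  xyz_a <- as.matrix(at[ia, c("x", "y", "z")])
  xyz_b <- as.matrix(at[ib, c("x", "y", "z")])
  el_a <- at$element[ia]
  el_b <- at$element[ib]
  unknown <- setdiff(toupper(unique(c(el_a, el_b))), names(vdw_radii))
  if (length(unknown))
    stop("buried_interface_area: no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  # quick reject: bounding-sphere style contact test
  rmax <- max(vdw_radii[toupper(c(el_a, el_b))]) + probe
  mind2 <- min(vapply(seq_len(nrow(xyz_a)), function(i)
    min(rowSums(sweep(xyz_b, 2, xyz_a[i, ])^2)), numeric(1)))
  if (mind2 > (2 * rmax)^2) return(0)
  sa <- sum(sasa_atoms(xyz_a, el_a, probe, points_per_atom))
  sb <- sum(sasa_atoms(xyz_b, el_b, probe, points_per_atom))
  sab <- sum(sasa_atoms(rbind(xyz_a, xyz_b), c(el_a, el_b), probe,
                        points_per_atom))
  (sa + sb - sab) / 2
}

# Average residue masses (Da), Expasy-style; water 18.01528.
residue_masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                    C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                    H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                    M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                    T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
water_mass <- 18.01528

#' Average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water; no post-translational
#' modifications. The empty sequence returns the mass of water.
#'
#' @param sequence one-letter amino-acid string (20 standard letters).
#' @return mass in Dalton.
#' @examples
#' sequence_average_mass("G") # 75.07, free glycine
#' @export
sequence_average_mass <- function(sequence) {
  if (length(sequence) > 1) sequence <- paste(sequence, collapse = "")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) return(water_mass)
  bad <- which(!(letters1 %in% names(residue_masses)))
  if (length(bad))
    stop(sprintf("sequence_average_mass: unknown residue '%s' at position %d",
                 letters1[bad[1]], bad[1]))
  sum(residue_masses[letters1]) + water_mass
}

#' Domain ranges
#'
#' Named residue intervals (inclusive, full-length numbering), e.g. the
#' protease (M12A), adhesion (MAM) and TRAF-homology (MATH) domains plus the
#' pro-domain of a meprin-like protein. Intervals must not overlap.
#'
#' @param ... named length-2 integer vectors `c(start, end)`.
#' @return an object of class `domain_ranges`.
#' @export
domain_ranges <- function(...) {
  rg <- list(...)
  if (!length(rg) || is.null(names(rg)) || any(names(rg) == ""))
    stop("domain_ranges: all ranges must be named")
  for (nm in names(rg)) {
    r <- rg[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop("domain_ranges: range '", nm, "' must be c(start, end) with start <= end")
  }
  if (length(rg) > 1) {
    for (i in seq_along(rg)) for (j in seq_len(i - 1L)) {
      if (rg[[i]][1] <= rg[[j]][2] && rg[[j]][1] <= rg[[i]][2])
        stop("domain_ranges: ranges '", names(rg)[j], "' and '", names(rg)[i],
             "' overlap")
    }
  }
  structure(rg, class = "domain_ranges")
}

#' Count mutated residues per domain
#'
#' Buckets residue numbers into domain ranges; each residue lands in exactly
#' one bucket, residues outside every range in `unassigned`. Totals are
#' conserved.
#'
#' @param residue_numbers positive integer vector (repeats allowed; each
#'   occurrence counts).
#' @param ranges a [domain_ranges()].
#' @return named integer vector of counts (one per domain plus
#'   `unassigned`).
#' @export
mutations_per_domain <- function(residue_numbers, ranges) {
  stopifnot(inherits(ranges, "domain_ranges"))
  if (length(residue_numbers) && any(residue_numbers <= 0))
    stop("mutations_per_domain: residue numbers must be positive")
  counts <- stats::setNames(integer(length(ranges) + 1L),
                            c(names(ranges), "unassigned"))
  for (rn in residue_numbers) {
    hit <- which(vapply(ranges, function(r) rn >= r[1] && rn <= r[2], logical(1)))
    if (length(hit)) counts[hit[1]] <- counts[hit[1]] + 1L
    else counts["unassigned"] <- counts["unassigned"] + 1L
  }
  counts
}
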