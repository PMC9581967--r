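#' Simulation configuration
#'
#' @param pixel_size Angstrom per pixel (> 0).
#' @param micrograph_shape edge length of the square micrograph (px, even).
#' @param snr ratio of signal variance to noise variance measured within the
#'   filament footprint (`Inf` disables noise; >= 0).
#' @param ctf a [ctf_params()] or `NULL` to disable CTF modulation.
#' @param filaments_per_micrograph count.
#' @param defocus_range length-2 range (Angstrom); [simulate_dataset()]
#'   draws each micrograph's defocus uniformly from it so CTF zeros fill in
#'   across the dataset (`NULL` keeps `ctf`'s defocus fixed).
#' @param noise_sd noise standard deviation used when a micrograph contains
#'   no signal (picker false-positive tests).
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   micrographs and truth tables.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(pixel_size = 4, micrograph_shape = 512,
                              snr = 2, ctf = ctf_params(),
                              filaments_per_micrograph = 4,
                              defocus_range = c(8000, 16000),
                              noise_sd = 1, seed = 1) {
  if (pixel_size <= 0) stop("simulation_config: pixel_size must be > 0")
  if (is.na(snr) || snr < 0) stop("simulation_config: snr must be >= 0")
  structure(list(pixel_size = pixel_size,
                 micrograph_shape = as.integer(micrograph_shape),
                 snr = snr, ctf = ctf,
                 filaments_per_micrograph = as.integer(filaments_per_micrograph),
                 defocus_range = defocus_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Instantiate a filament in the micrograph frame
#'
#' Places a (possibly flexible) filament: lattice-frame unit transforms are
#' rotated so the helix axis lies in the micrograph plane along
#' `direction_deg`, rolled about its own axis by `roll_deg`, and centred at
#' `centre` (Angstrom, centred micrograph frame).
#'
#' @param lattice a [helical_lattice()].
#' @param n_units number of asymmetric units.
#' @param flex `NULL` or [flex_params()].
#' @param centre length-2 in-plane centre (Angstrom).
#' @param direction_deg in-plane axis direction (degrees).
#' @param roll_deg rotation about the filament axis (degrees).
#' @param truth_id identifier string.
#' @return an object of class `filament_instance` with fields `unit_poses`
#'   (micrograph frame), `backbone` (3D polyline, micrograph frame),
#'   `frame` (the placement rotation), `arc0` (axial position of the
#'   filament midpoint in the lattice frame), `lattice`, `flex`, `truth_id`.
#' @export
filament_instance <- function(lattice, n_units = lattice$units_per_filament,
                              flex = NULL, centre = c(0, 0),
                              direction_deg = 0, roll_deg = 0,
                              truth_id = "fil") {
  trs <- lattice_poses(lattice, n_units, flex)
  # axial extent -> centre the filament on its mid axial point
  zmid <- (trs[[1]]$t[3] + trs[[length(trs)]]$t[3]) / 2
  Rf <- rot_z(direction_deg) %*% rot_y(90) %*% rot_z(roll_deg)
  shift3 <- c(centre[1], centre[2], 0)
  unit_poses <- lapply(trs, function(tr) {
    list(R = Rf %*% tr$R,
         t = as.vector(Rf %*% (tr$t - c(0, 0, zmid)) + shift3))
  })
  # backbone: axis polyline sampled at each unit's axial position
  backbone <- t(vapply(trs, function(tr) {
    axis_pt <- tr$t - as.vector(tr$R %*% c(lattice$radius, 0, 0))
    as.vector(Rf %*% (axis_pt - c(0, 0, zmid)) + shift3)
  }, numeric(3)))
  structure(list(unit_poses = unit_poses, backbone = backbone, frame = Rf,
                 roll_deg = roll_deg, direction_deg = direction_deg,
                 arc0 = zmid, lattice = lattice, flex = flex,
                 truth_id = truth_id),
            class = "filament_instance")
}

# Analytic projection of the pseudo-atom model: a 3D Gaussian of sigma s and
# peak w integrates along z (in voxel units) to a 2D Gaussian of amplitude
# w * s * sqrt(2*pi) / apix.
splat_projection <- function(instances, unit, n, apix) {
  img <- matrix(0, n, n)
  ax <- axis_coords(n, apix)
  at <- unit$pseudo_atoms
  for (inst in instances) {
    for (up in inst$unit_poses) {
      pos <- up$R %*% t(as.matrix(at[, c("x", "y", "z")])) + up$t
      for (a in seq_len(nrow(at))) {
        p <- pos[, a]
        sg <- at$width[a]
        amp <- at$weight[a] * sg * sqrt(2 * pi) / apix
        ix <- which(ax >= p[1] - 4 * sg & ax <= p[1] + 4 * sg)
        iy <- which(ax >= p[2] - 4 * sg & ax <= p[2] + 4 * sg)
        if (!length(ix) || !length(iy)) next
        img[ix, iy] <- img[ix, iy] +
          amp * outer(exp(-(ax[ix] - p[1])^2 / (2 * sg^2)),
                      exp(-(ax[iy] - p[2])^2 / (2 * sg^2)))
      }
    }
  }
  img
}

# Footprint: pixels within `radius_a` of any projected backbone point.
filament_footprint <- function(instances, n, apix, radius_a) {
  mask <- matrix(FALSE, n, n)
  cen <- n / 2 + 1
  r_px <- ceiling(radius_a / apix)
  disk <- outer((-r_px):r_px, (-r_px):r_px,
                function(i, j) i^2 + j^2 <= r_px^2)
  dsz <- 2L * r_px + 1L
  for (inst in instances) {
    bb <- inst$backbone
    # densify the polyline to ~2 px steps
    seg <- lapply(seq_len(nrow(bb) - 1L), function(i) {
      d <- sqrt(sum((bb[i + 1L, 1:2] - bb[i, 1:2])^2))
      tt <- seq(0, 1, length.out = max(2L, ceiling(d / (2 * apix))))
      cbind(bb[i, 1] + tt * (bb[i + 1L, 1] - bb[i, 1]),
            bb[i, 2] + tt * (bb[i + 1L, 2] - bb[i, 2]))
    })
    pts <- unique(round(do.call(rbind, seg) / apix) + cen)
    for (q in seq_len(nrow(pts))) {
      i0 <- pts[q, 1] - r_px; j0 <- pts[q, 2] - r_px
      ilo <- max(1L, i0); ihi <- min(n, i0 + dsz - 1L)
      jlo <- max(1L, j0); jhi <- min(n, j0 + dsz - 1L)
      if (ilo > ihi || jlo > jhi) next
      ii <- seq.int(ilo, ihi)
      jj <- seq.int(jlo, jhi)
      mask[ii, jj] <- mask[ii, jj] | disk[ii - i0 + 1L, jj - j0 + 1L]
    }
  }
  mask
}

#' Simulate a micrograph with ground truth
#'
#' Renders the analytic projections of all filament instances, applies the
#' CTF by Fourier multiplication, and adds white Gaussian noise scaled so
#' that the variance ratio of (CTF-modulated) signal to noise within the
#' filament footprint equals `cfg$snr`. An empty instance list yields a
#' noise-only micrograph (sd `cfg$noise_sd`) and empty truth tables.
#'
#' @param instances list of [filament_instance()]s.
#' @param unit an [asym_unit_model()].
#' @param cfg a [simulation_config()].
#' @param micrograph_id identifier recorded in the truth tables.
#' @return list with `micrograph` ([image2d()]), `truth` (named list of
#'   data.frames: `units` with per-unit poses, `filaments` with backbone
#'   polylines and placement angles), and `footprint` (logical matrix).
#' @export
simulate_micrograph <- function(instances, unit, cfg, micrograph_id = "mic") {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$micrograph_shape
  apix <- cfg$pixel_size
  clean <- splat_projection(instances, unit, n, apix)
  if (!is.null(cfg$ctf) && length(instances)) {
    cimg <- ctf_image(cfg$ctf, n, apix)
    clean <- Re(ifft_centered(fft_centered(clean) * cimg))
  }
  if (length(instances)) {
    foot_r <- max_instance_radius(instances, unit)
    foot <- filament_footprint(instances, n, apix, foot_r)
    sig_var <- stats::var(clean[foot])
    noise_sd <- if (is.infinite(cfg$snr)) 0 else if (cfg$snr == 0) cfg$noise_sd
    else sqrt(sig_var / cfg$snr)
  } else {
    foot <- matrix(FALSE, n, n)
    noise_sd <- cfg$noise_sd
  }
  img <- clean
  if (noise_sd > 0) {
    img <- img + withr::with_seed(cfg$seed,
      matrix(stats::rnorm(n * n, 0, noise_sd), n, n))
  }
  truth <- truth_tables(instances, cfg, micrograph_id, noise_sd)
  list(micrograph = image2d(img, apix), truth = truth, footprint = foot,
       clean = image2d(clean, apix), ctf = cfg$ctf)
}

max_instance_radius <- function(instances, unit) {
  at <- unit$pseudo_atoms
  ext <- max(sqrt(at$x^2 + at$y^2 + at$z^2) + 3 * at$width)
  max(vapply(instances, function(i) i$lattice$radius, numeric(1))) + ext
}

truth_tables <- function(instances, cfg, micrograph_id, noise_sd) {
  if (!length(instances)) {
    return(list(units = data.frame(), filaments = data.frame()))
  }
  units <- do.call(rbind, lapply(instances, function(inst) {
    eu <- t(vapply(inst$unit_poses, function(up) matrix_to_euler(up$R), numeric(3)))
    tt <- t(vapply(inst$unit_poses, function(up) up$t, numeric(3)))
    data.frame(micrograph_id = micrograph_id, filament_id = inst$truth_id,
               unit_index = seq_len(nrow(eu)) - 1L,
               rot = eu[, 1], tilt = eu[, 2], psi = eu[, 3],
               x = tt[, 1], y = tt[, 2], z = tt[, 3])
  }))
  units$defocus_u <- if (is.null(cfg$ctf)) 0 else cfg$ctf$defocus_u
  units$defocus_v <- if (is.null(cfg$ctf)) 0 else cfg$ctf$defocus_v
  units$seed <- cfg$seed
  units$noise_sd <- noise_sd
  filaments <- do.call(rbind, lapply(instances, function(inst) {
    data.frame(micrograph_id = micrograph_id, filament_id = inst$truth_id,
               point_index = seq_len(nrow(inst$backbone)) - 1L,
               x = inst$backbone[, 1], y = inst$backbone[, 2],
               z = inst$backbone[, 3],
               direction_deg = inst$direction_deg, roll_deg = inst$roll_deg)
  }))
  list(units = units, filaments = filaments)
}

#' Simulate a multi-micrograph dataset
#'
#' Convenience wrapper: lays filaments on non-overlapping lanes of each
#' micrograph with randomised direction, roll and flexibility seed, and
#' returns micrographs plus concatenated truth tables.
#'
#' @param lattice,unit,cfg see [simulate_micrograph()].
#' @param n_micrographs count.
#' @param n_units units per filament.
#' @param flex `NULL` or a [flex_params()]; its seed is re-derived per
#'   filament from `cfg$seed`.
#' @return list with `micrographs` (list), `truth` (merged tables),
#'   `instances` (list of lists).
#' @export
simulate_dataset <- function(lattice, unit, cfg, n_micrographs = 2,
                             n_units = lattice$units_per_filament,
                             flex = NULL) {
  mics <- vector("list", n_micrographs)
  all_units <- list()
  all_fil <- list()
  instances <- vector("list", n_micrographs)
  nf <- cfg$filaments_per_micrograph
  extent_a <- cfg$micrograph_shape * cfg$pixel_size
  lane <- extent_a / (nf + 1)
  for (m in seq_len(n_micrographs)) {
    pars <- withr::with_seed(cfg$seed + 7919L * m, {
      data.frame(dir = stats::runif(nf, -8, 8),
                 roll = stats::runif(nf, 0, 360),
                 jitter = stats::runif(nf, -0.2, 0.2),
                 fseed = sample.int(2^30, nf))
    })
    inst <- lapply(seq_len(nf), function(i) {
      fl <- flex
      if (!is.null(fl)) fl$seed <- pars$fseed[i]
      filament_instance(lattice, n_units, fl,
                        centre = c(0, (i - (nf + 1) / 2) * lane * (1 + pars$jitter[i] * 0.1)),
                        direction_deg = pars$dir[i], roll_deg = pars$roll[i],
                        truth_id = sprintf("m%02d_f%02d", m, i))
    })
    mic_id <- sprintf("mic%03d", m)
    cfg_m <- cfg
    cfg_m$seed <- cfg$seed + 104729L * m
    if (!is.null(cfg$ctf) && !is.null(cfg$defocus_range)) {
      df <- withr::with_seed(cfg$seed + 15485863L * m,
                             stats::runif(1, cfg$defocus_range[1], cfg$defocus_range[2]))
      cfg_m$ctf$defocus_u <- cfg_m$ctf$defocus_v <- df
    }
    sim <- simulate_micrograph(inst, unit, cfg_m, micrograph_id = mic_id)
    mics[[m]] <- sim
    all_units[[m]] <- sim$truth$units
    all_fil[[m]] <- sim$truth$filaments
    instances[[m]] <- inst
  }
  list(micrographs = mics,
       truth = list(units = do.call(rbind, all_units),
                    filaments = do.call(rbind, all_fil)),
       instances = instances)
}
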