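#' Helical lattice parameterization
#'
#' Rise/twist/radius description of a filament built from one repeating
#' asymmetric unit (here a C2 homodimer). Negative twist generates a
#' left-handed lattice.
#'
#' @param rise axial translation per asymmetric unit (Angstrom, > 0).
#' @param twist azimuthal rotation per unit (degrees, |twist| < 360; signed,
#'   negative = left-handed).
#' @param radius distance of the lattice point from the helical axis
#'   (Angstrom, >= 0).
#' @param units_per_filament default number of units when instantiating
#'   filaments.
#' @return an object of class `helical_lattice`.
#' @export
helical_lattice <- function(rise, twist, radius, units_per_filament = 60) {
  v <- c(rise, twist, radius, units_per_filament)
  if (!all(is.finite(v))) stop("helical_lattice: non-finite parameters")
  if (rise <= 0) stop("helical_lattice: rise must be > 0")
  if (abs(twist) >= 360) stop("helical_lattice: |twist| must be < 360")
  if (radius < 0) stop("helical_lattice: radius must be >= 0")
  structure(list(rise = rise, twist = twist, radius = radius,
                 units_per_filament = as.integer(units_per_filament)),
            class = "helical_lattice")
}

#' Demonstration lattice and dimer model
#'
#' Desk-scale stand-in for a meprin-alpha-like filament. The published
#' envelope (outer diameter ~22 nm, lumen ~15 nm, groove ~7 nm, active-site
#' spacing ~8 nm) constrains the lattice but rise and twist themselves are
#' inferred, not measured: `demo_lattice()` uses radius 92.5 A, twist -49
#' degrees (left-handed, ~7.3 dimers/turn) and rise 15 A (pitch 110 A), which
#' reproduces that envelope. `demo_asym_unit()` is a coarse pseudo-atom C2
#' dimer: an inward protease-like lobe (lumen side) and two outer
#' adhesion-domain lobes, C2-symmetric about the radial axis.
#'
#' @return a `helical_lattice` / `asym_unit_model`.
#' @export
demo_lattice <- function() helical_lattice(rise = 15, twist = -49, radius = 92.5)

#' @rdname demo_lattice
#' @export
demo_asym_unit <- function() {
  # three domain centres per monomer (x radial, z axial), each a cluster of
  # four narrow Gaussians: narrow widths give the phantom genuine signal out
  # to the working Nyquist frequency, as an atomic structure would
  centres <- data.frame(
    x = c(-13, 8, 13),
    y = c(5, 9, -4),
    z = c(6, 5, 3)
  )
  offs <- list(
    rbind(c(0, 0, 0), c(3, 2, -3), c(-2, 4, 2), c(-1, -5, -3)),
    rbind(c(0, 0, 0), c(-2, 5, 2), c(2, -2, -4), c(1, 4, 3)),
    rbind(c(0, 0, 0), c(2, -4, 3), c(-3, -1, -2), c(1, 5, -4))
  )
  wts <- c(1.2, 0.9, 0.9, 0.8)
  half <- do.call(rbind, lapply(1:3, function(d) {
    data.frame(x = centres$x[d] + offs[[d]][, 1],
               y = centres$y[d] + offs[[d]][, 2],
               z = centres$z[d] + offs[[d]][, 3],
               weight = wts, width = 3.8)
  }))
  other <- transform(half, y = -y, z = -z) # C2 about the radial (x) axis
  asym_unit_model(rbind(half, other))
}

#' Pseudo-atom model of the repeating asymmetric unit
#'
#' @param pseudo_atoms data.frame with columns `x, y, z` (Angstrom, unit
#'   frame: x radial, z axial), `weight` (> 0) and `width` (Gaussian sigma,
#'   Angstrom, > 0).
#' @return an object of class `asym_unit_model`.
#' @export
asym_unit_model <- function(pseudo_atoms) {
  need <- c("x", "y", "z", "weight", "width")
  if (!all(need %in% names(pseudo_atoms)))
    stop("asym_unit_model: pseudo_atoms needs columns ", paste(need, collapse = ", "))
  if (nrow(pseudo_atoms) < 1L) stop("asym_unit_model: at least one pseudo-atom")
  if (any(pseudo_atoms$weight <= 0)) stop("asym_unit_model: weights must be > 0")
  if (any(pseudo_atoms$width <= 0)) stop("asym_unit_model: widths must be > 0")
  structure(list(pseudo_atoms = pseudo_atoms), class = "asym_unit_model")
}

#' Continuous-flexibility parameters
#'
#' Interpretable knobs reproducing the bend / expand / contract motions of an
#' intrinsically flexible filament: a circular-arc backbone of constant
#' curvature `bend_rate`, plus smooth per-unit modulation of twist and rise.
#' The modulations are correlated over `corr_length` units (Gaussian-kernel
#' smoothed noise) and accumulate along the filament, so the lattice stays
#' locally near-ideal — neighbouring dimers keep their geometry — while the
#' accumulated phase drifts by many degrees across a segment box, which is
#' what defeats global alignment of continuously flexible filaments.
#'
#' @param bend_rate backbone curvature (degrees per 100 Angstrom, >= 0).
#' @param twist_jitter_sd sd of the smooth per-unit twist deviation (deg).
#' @param rise_jitter_sd sd of the smooth per-unit rise deviation (Angstrom).
#' @param corr_length correlation length of the deviations (units); 0 gives
#'   white (unit-to-unit independent) jitter.
#' @param seed integer seed; identical seed gives an identical filament.
#' @return an object of class `flex_params`.
#' @export
flex_params <- function(bend_rate = 4, twist_jitter_sd = 2,
                        rise_jitter_sd = 1, corr_length = 20, seed = 1) {
  if (any(c(bend_rate, twist_jitter_sd, rise_jitter_sd, corr_length) < 0))
    stop("flex_params: rates, sds and corr_length must be >= 0")
  structure(list(bend_rate = bend_rate, twist_jitter_sd = twist_jitter_sd,
                 rise_jitter_sd = rise_jitter_sd, corr_length = corr_length,
                 seed = as.integer(seed)),
            class = "flex_params")
}

# Smooth standardized noise: white noise convolved with a Gaussian kernel of
# width `corr` (units), rescaled to unit variance.
smooth_noise <- function(n, corr) {
  z <- stats::rnorm(n + 6 * max(1, ceiling(corr)))
  if (corr <= 0) return(z[seq_len(n)])
  k <- stats::dnorm(seq(-3 * corr, 3 * corr), sd = corr)
  s <- stats::filter(z, k / sum(k), sides = 2)
  s <- s[!is.na(s)][seq_len(n)]
  s / stats::sd(s)
}

#' Rigid transforms of the lattice units
#'
#' Unit k (k = 0 .. n_units-1) sits at azimuth `k * twist` (plus accumulated
#' jitter), axial position `k * rise` (plus accumulated jitter), at `radius`
#' from the (possibly arc-bent) backbone. With `flex = NULL` the lattice is
#' exactly helical: applying the `(twist, rise)` symmetry operator to unit
#' k's transform reproduces unit k+1's transform.
#'
#' @param lattice a [helical_lattice()].
#' @param n_units number of units (>= 1).
#' @param flex `NULL` (rigid) or a [flex_params()].
#' @return list of transforms, each `list(R = 3x3, t = length-3)` mapping the
#'   unit frame into the filament frame (helix axis = z, unit 0 at azimuth 0,
#'   z = 0).
#' @export
lattice_poses <- function(lattice, n_units, flex = NULL) {
  stopifnot(inherits(lattice, "helical_lattice"))
  if (!is.finite(n_units) || n_units < 1) stop("lattice_poses: n_units must be >= 1")
  n_units <- as.integer(n_units)
  if (is.null(flex)) {
    alphas <- (seq_len(n_units) - 1) * lattice$twist
    zs <- (seq_len(n_units) - 1) * lattice$rise
    bend_dir <- 0
    kappa <- 0
  } else {
    cl <- if (is.null(flex$corr_length)) 0 else flex$corr_length
    incr <- withr::with_seed(flex$seed, {
      list(twist = flex$twist_jitter_sd * smooth_noise(n_units - 1, cl),
           rise = flex$rise_jitter_sd * smooth_noise(n_units - 1, cl),
           dir = stats::runif(1, 0, 360))
    })
    alphas <- cumsum(c(0, lattice$twist + incr$twist))
    zs <- cumsum(c(0, pmax(lattice$rise + incr$rise, 0.1 * lattice$rise)))
    bend_dir <- incr$dir
    kappa <- deg2rad(flex$bend_rate) / 100 # rad per Angstrom
  }
  lapply(seq_len(n_units), function(k) {
    Rz <- rot_z(alphas[k])
    axis_point <- c(0, 0, zs[k])
    B <- diag(3)
    if (kappa > 0) {
      s <- zs[k]
      # circular arc in the plane spanned by z and the bend direction
      e_b <- c(cos(deg2rad(bend_dir)), sin(deg2rad(bend_dir)), 0)
      rho <- 1 / kappa
      axis_point <- rho * (1 - cos(s * kappa)) * e_b + c(0, 0, rho * sin(s * kappa))
      B <- rotation_about_axis(cross3(c(0, 0, 1), e_b), s * kappa * 180 / pi)
    }
    R <- B %*% Rz
    t <- axis_point + R %*% c(lattice$radius, 0, 0)
    list(R = R, t = as.vector(t))
  })
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation about (possibly unnormalized) axis by angle in degrees.
rotation_about_axis <- function(axis, deg) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) return(diag(3))
  u <- axis / nrm
  a <- deg2rad(deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Handedness of a set of lattice transforms
#'
#' Sign of the axial component of the cross product of successive radial
#' vectors (projected perpendicular to z), i.e. the screw sense: negative for
#' a left-handed lattice, matching the sign of twist.
#'
#' @param transforms list of transforms from [lattice_poses()].
#' @return -1 (left-handed), +1 (right-handed) or 0 (degenerate).
#' @export
lattice_handedness <- function(transforms) {
  if (length(transforms) < 2L) return(0)
  signs <- vapply(seq_len(length(transforms) - 1L), function(k) {
    r1 <- transforms[[k]]$t
    r2 <- transforms[[k + 1L]]$t
    r1[3] <- 0; r2[3] <- 0
    sign(cross3(r1, r2)[3])
  }, numeric(1))
  sign(sum(signs))
}

#' Helical symmetry operator
#'
#' The rigid transform `(Rz(twist), rise * z)` of the lattice; applying it to
#' unit k's transform gives unit k+1's transform on a rigid lattice.
#'
#' @param lattice a [helical_lattice()].
#' @param k number of applications (may be negative).
#' @return `list(R, t)`.
#' @export
symmetry_operator <- function(lattice, k = 1) {
  list(R = rot_z(k * lattice$twist), t = c(0, 0, k * lattice$rise))
}

#' Apply a rigid transform to another
#'
#' `compose_transform(S, T)` returns the transform "first T, then S".
#'
#' @param s,t transforms `list(R, t)`.
#' @export
compose_transform <- function(s, t) {
  list(R = s$R %*% t$R, t = as.vector(s$R %*% t$t + s$t))
}
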