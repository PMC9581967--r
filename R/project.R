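#' Fourier-slice projector
#'
#' Precomputes the gridding-corrected, 2x zero-padded, centred Fourier
#' transform of a map so that many central slices (projections) can be
#' extracted cheaply. [project()] is the one-shot convenience wrapper.
#'
#' The projection at a pose equals the line integral (sum, in voxel units) of
#' the rotated map along +z, then translated by the pose shifts.
#'
#' @param map a [density_map()].
#' @return an object of class `projector`.
#' @export
projector <- function(map) {
  stopifnot(inherits(map, "density_map"))
  n <- box_size(map)
  m <- 2L * n
  # gridding pre-correction for trilinear slice interpolation
  corr <- gridding_correction_1d(n, m)
  v <- map$values / outer(outer(corr, corr), corr)
  pad <- array(0, dim = c(m, m, m))
  off <- n %/% 2L
  pad[off + seq_len(n), off + seq_len(n), off + seq_len(n)] <- v
  structure(list(fvol = fft_centered(pad), n = n, m = m, apix = map$apix),
            class = "projector")
}

# Fractional 0-based gather coordinates for the central slice of pose R:
# n^2 points on the oversampled m-grid, in natural (DC-first) slice order.
slice_coords <- function(prj, R) {
  n <- prj$n
  h <- freq_index_natural(n)
  kx <- rep(h, times = n)
  ky <- rep(h, each = n)
  q <- t(R) %*% rbind(2 * kx, 2 * ky, 0) # oversampling factor 2
  # to 0-based array indices: centred index 0 lives at 0-based m/2
  t(q + prj$m / 2)
}

# Fourier transform (natural order) of the projection at `p` (one-row pose).
project_slice_ft <- function(prj, p) {
  n <- prj$n
  S <- project_slice_ft_bare(prj, p$rot[1], p$tilt[1], p$psi[1])
  sx <- p$shift_x[1] / prj$apix
  sy <- p$shift_y[1] / prj$apix
  if (sx != 0 || sy != 0) {
    f <- freq_index_natural(n) / n
    S <- S * exp(-2i * pi * (outer(f * sx, f * sy, `+`)))
  }
  S
}

# Natural-order slice from raw angles.
project_slice_ft_bare <- function(prj, rot, tilt, psi) {
  R <- rot_z(psi) %*% rot_y(tilt) %*% rot_z(rot)
  matrix(cpp_trilinear_gather(prj$fvol, dim(prj$fvol), slice_coords(prj, R)),
         prj$n, prj$n)
}

# Inverse FFT of a natural-order spectrum to a centred real-space image.
ifft_natural_to_centered <- function(S) {
  fftshift(stats::fft(S, inverse = TRUE)) / length(S)
}

#' Project a map at a pose
#'
#' Central-slice projection with 2x-oversampled trilinear Fourier
#' interpolation and gridding correction. Linear in the map. For repeated
#' projections of one map build a [projector()] once and call
#' `project(prj, pose)` with it.
#'
#' @param map a [density_map()] or a [projector()].
#' @param p a one-row pose data.frame (see [pose()]).
#' @return an [image2d()] of the same edge length and pixel size.
#' @export
project <- function(map, p) {
  check_poses(p, 1L)
  prj <- if (inherits(map, "projector")) map else projector(map)
  img <- Re(ifft_natural_to_centered(project_slice_ft(prj, p)))
  image2d(img, prj$apix)
}

# In-plane rotation of a square image about its centred origin by `deg`
# (a point at x moves to Rz(deg) x), bilinear interpolation, zero fill.
rotate_image <- function(values, deg) {
  n <- nrow(values)
  a <- deg2rad(deg)
  ca <- cos(a); sa <- sin(a)
  cen <- n / 2 + 1
  x <- rep(seq_len(n) - cen, times = n)
  y <- rep(seq_len(n) - cen, each = n)
  # sample source at Rz(-deg) (x, y)
  xs <- ca * x + sa * y + cen
  ys <- -sa * x + ca * y + cen
  bilinear_gather(values, xs, ys)
}

# Vectorised bilinear sampling of matrix `v` at 1-based fractional (xs, ys);
# out-of-range samples are 0.
bilinear_gather <- function(v, xs, ys) {
  n1 <- nrow(v); n2 <- ncol(v)
  i0 <- floor(xs); j0 <- floor(ys)
  fx <- xs - i0; fy <- ys - j0
  ok <- i0 >= 1 & j0 >= 1 & i0 + 1 <= n1 & j0 + 1 <= n2
  out <- numeric(length(xs))
  i0k <- i0[ok]; j0k <- j0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  id <- function(i, j) (j - 1L) * n1 + i
  out[ok] <- v[id(i0k, j0k)] * (1 - fxk) * (1 - fyk) +
    v[id(i0k + 1L, j0k)] * fxk * (1 - fyk) +
    v[id(i0k, j0k + 1L)] * (1 - fxk) * fyk +
    v[id(i0k + 1L, j0k + 1L)] * fxk * fyk
  matrix(out, n1, n2)
}
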