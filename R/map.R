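#' Density map and image containers
#'
#' A `density_map` is a cubic voxel grid with a physical pixel size; an
#' `image2d` is its 2D counterpart. Both use the centred-origin convention:
#' for an even edge length `n` the physical origin sits at 1-based index
#' `n/2 + 1` along each axis. All sizes are Angstrom.
#'
#' @param values numeric 3D array (cubic, even edge) or 2D matrix (square,
#'   even edge).
#' @param apix pixel size in Angstrom per voxel/pixel (> 0).
#' @return An object of class `density_map` or `image2d`: a list with
#'   elements `values` and `apix`.
#' @examples
#' m <- density_map(array(0, c(8, 8, 8)), apix = 2)
#' box_size(m)
#' @export
density_map <- function(values, apix) {
  d <- dim(values)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("density_map: `values` must be a cubic 3D array")
  if (d[1] %% 2L != 0L)
    stop("density_map: edge length must be even")
  if (!is.numeric(apix) || length(apix) != 1L || !is.finite(apix) || apix <= 0)
    stop("density_map: `apix` must be a single positive number")
  if (!all(is.finite(values)))
    stop("density_map: non-finite voxel values")
  structure(list(values = values, apix = apix), class = "density_map")
}

#' @rdname density_map
#' @export
image2d <- function(values, apix) {
  d <- dim(values)
  if (length(d) != 2L || d[1] != d[2])
    stop("image2d: `values` must be a square matrix")
  if (d[1] %% 2L != 0L)
    stop("image2d: edge length must be even")
  if (!is.numeric(apix) || length(apix) != 1L || !is.finite(apix) || apix <= 0)
    stop("image2d: `apix` must be a single positive number")
  if (!all(is.finite(values)))
    stop("image2d: non-finite pixel values")
  structure(list(values = values, apix = apix), class = "image2d")
}

#' @rdname density_map
#' @param x a `density_map` or `image2d`.
#' @export
box_size <- function(x) dim(x$values)[1]

#' @export
print.density_map <- function(x, ...) {
  n <- box_size(x)
  cat(sprintf("<density_map %d^3 voxels, %.3f A/px (%.1f A box)>\n",
              n, x$apix, n * x$apix))
  invisible(x)
}

#' @export
print.image2d <- function(x, ...) {
  n <- box_size(x)
  cat(sprintf("<image2d %d^2 px, %.3f A/px>\n", n, x$apix))
  invisible(x)
}

# Physical centred coordinates (A) along one axis of an n-box.
axis_coords <- function(n, apix) freq_index(n) * apix

#' Soft-edged spherical or cylindrical mask
#'
#' Builds a map with value 1 inside `radius - soft_edge`, a half-cosine ramp
#' across the edge, and 0 at and beyond `radius`. Used for reference masking
#' before projection matching and for FSC masking.
#'
#' @param n box edge (voxels).
#' @param apix pixel size (A).
#' @param radius outer radius (A) at which the mask reaches 0.
#' @param soft_edge ramp width (A) inside `radius`.
#' @param centre physical centre (A, length-3), default the box origin.
#' @param shape `"sphere"` or `"cylinder"` (axis = z).
#' @return a `density_map` with values in \[0, 1\].
#' @export
soft_mask <- function(n, apix, radius, soft_edge = 5 * apix,
                      centre = c(0, 0, 0), shape = c("sphere", "cylinder")) {
  shape <- match.arg(shape)
  ax <- axis_coords(n, apix)
  dx2 <- (ax - centre[1])^2
  dy2 <- (ax - centre[2])^2
  dz2 <- (ax - centre[3])^2
  r2 <- outer(dx2, dy2, `+`)
  r <- if (shape == "sphere") {
    sqrt(array(outer(as.vector(r2), dz2, `+`), dim = c(n, n, n)))
  } else {
    array(rep(sqrt(r2), n), dim = c(n, n, n))
  }
  density_map(mask_profile(r, radius, soft_edge), apix)
}

# Radial soft profile: 1 inside radius - soft_edge, cosine ramp, 0 at radius.
mask_profile <- function(r, radius, soft_edge) {
  t <- (r - (radius - soft_edge)) / soft_edge
  0.5 * (1 + cos(pi * pmin(pmax(t, 0), 1)))
}

#' Fourier-crop binning
#'
#' Downsamples a map or image by an integer factor by cropping its centred
#' Fourier transform — the standard binning used to accelerate coarse
#' alignment. The pixel size is multiplied by the factor.
#'
#' @param x a [density_map()] or [image2d()].
#' @param f integer factor (>= 1); the binned edge must be even.
#' @return an object of the same class.
#' @export
bin_fourier <- function(x, f) {
  f <- as.integer(f)
  if (f <= 1L) return(x)
  n <- box_size(x)
  n2 <- n %/% f
  if (n2 %% 2L != 0L || n2 * f != n) stop("bin_fourier: incompatible factor")
  F <- fft_centered(x$values)
  off <- (n - n2) %/% 2L
  idx <- off + seq_len(n2)
  Fb <- if (length(dim(x$values)) == 3L) F[idx, idx, idx] else F[idx, idx]
  vals <- Re(ifft_centered(Fb)) # per-element inverse keeps densities comparable
  if (length(dim(x$values)) == 3L) density_map(vals, x$apix * f)
  else image2d(vals, x$apix * f)
}

#' Low-pass filter a map or image
#'
#' Cosine-edged low-pass at a resolution cutoff.
#'
#' @param x a `density_map` or `image2d`.
#' @param cutoff resolution cutoff (A).
#' @param width roll-off width in Fourier shells.
#' @return an object of the same class.
#' @export
lowpass <- function(x, cutoff, width = 2) {
  x$values <- lowpass_filter_values(x$values, x$apix, cutoff, width)
  x
}
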