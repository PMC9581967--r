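# Internal Fourier helpers. All public-facing grids use the "centred"
# convention: the origin voxel of an even-sized box of edge n sits at
# 1-based index n/2 + 1, and centred frequency indices run -n/2 .. n/2 - 1.

#' @useDynLib helixpsa, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

circshift <- function(x, s) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    return(x[((seq_len(n) - 1 - s) %% n) + 1])
  }
  ix <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  iy <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  if (length(d) == 2L) return(x[ix, iy, drop = FALSE])
  iz <- ((seq_len(d[3]) - 1 - s[3]) %% d[3]) + 1
  x[ix, iy, iz, drop = FALSE]
}

fftshift <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  circshift(x, floor(d / 2))
}

ifftshift <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  circshift(x, -floor(d / 2))
}

# Centred DFT: input/output both have the origin at n/2 + 1.
fft_centered <- function(x) fftshift(stats::fft(ifftshift(x)))

ifft_centered <- function(x) fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / length(x)

# Centred integer frequency indices for an even edge length.
freq_index <- function(n) seq.int(-n %/% 2, n %/% 2 - 1)

# Natural (DC-first) integer frequency indices, matching stats::fft order.
freq_index_natural <- function(n) c(seq.int(0, n %/% 2 - 1), seq.int(-n %/% 2, -1))

# Per-axis gridding correction for a trilinear kernel on a grid of period m:
# the kernel's real-space transform is sinc^2(x/m).
sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

gridding_correction_1d <- function(n, m) sinc(freq_index(n) / m)^2

# Radius (in centred index units) of every element of an n^2 or n^3 grid.
radius_grid_2d <- function(n) {
  h <- freq_index(n)
  sqrt(outer(h^2, h^2, `+`))
}

radius_grid_3d <- function(n) {
  h <- freq_index(n)
  r2 <- outer(h^2, h^2, `+`)
  sqrt(outer(as.vector(r2), h^2, `+`)) |> array(dim = c(n, n, n))
}

# Low-pass a cubic map (or square image) at `cutoff` Angstrom with a cosine
# roll-off of `width` Fourier shells (0 = hard cutoff).
lowpass_filter_values <- function(values, apix, cutoff, width = 2) {
  n <- dim(values)[1]
  r <- if (length(dim(values)) == 3) radius_grid_3d(n) else radius_grid_2d(n)
  r_cut <- n * apix / cutoff # shell index of the cutoff frequency
  filt <- if (width <= 0) (r <= r_cut) * 1 else
    0.5 * (1 + cos(pi * pmin(pmax((r - r_cut) / width, 0), 1)))
  Re(ifft_centered(fft_centered(values) * filt))
}
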