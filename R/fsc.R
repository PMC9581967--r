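#' Fourier shell correlation between two maps
#'
#' Per-shell normalized cross-correlation of Fourier coefficients, shells of
#' one Fourier voxel width up to Nyquist. An optional real-space mask is
#' applied to both maps first.
#'
#' @param map_a,map_b [density_map()]s on identical grids.
#' @param mask optional [density_map()] with values in \[0, 1\].
#' @return an `fsc_curve`: data.frame with columns `shell` (index),
#'   `frequency` (1/Angstrom, shell centre), `correlation`, `n_voxels`.
#'   Shells where either map has no power get correlation `NA`.
#' @export
fsc <- function(map_a, map_b, mask = NULL) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  n <- box_size(map_a)
  if (box_size(map_b) != n || map_a$apix != map_b$apix)
    stop("fsc: maps must share grid and pixel size")
  va <- map_a$values
  vb <- map_b$values
  if (!is.null(mask)) {
    if (box_size(mask) != n) stop("fsc: mask grid mismatch")
    va <- va * mask$values
    vb <- vb * mask$values
  }
  fa <- fft_centered(va)
  fb <- fft_centered(vb)
  shell <- round(radius_grid_3d(n))
  keep <- shell <= n %/% 2
  shell <- as.vector(shell[keep]) + 1L # 1-based bin
  num <- as.vector(Re(fa[keep] * Conj(fb[keep])))
  pa <- as.vector(Mod(fa[keep])^2)
  pb <- as.vector(Mod(fb[keep])^2)
  nb <- n %/% 2 + 1L
  s_num <- tapply_sum(num, shell, nb)
  s_pa <- tapply_sum(pa, shell, nb)
  s_pb <- tapply_sum(pb, shell, nb)
  denom <- sqrt(s_pa * s_pb)
  corr <- ifelse(denom > 0, s_num / denom, NA_real_)
  out <- data.frame(shell = 0:(nb - 1L),
                    frequency = (0:(nb - 1L)) / (n * map_a$apix),
                    correlation = corr,
                    n_voxels = tapply_sum(rep(1, length(shell)), shell, nb))
  class(out) <- c("fsc_curve", "data.frame")
  out
}

tapply_sum <- function(x, bin, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, bin)
  out[as.integer(rownames(s))] <- s
  out
}

#' Resolution at an FSC threshold
#'
#' Frequency of the first crossing of the curve below `threshold`, linearly
#' interpolated between shells; resolution is its reciprocal (Angstrom). If
#' the curve never drops below the threshold the Nyquist resolution
#' (2 x pixel size) is returned. If the curve is undefined (all-NA shells,
#' e.g. from an all-zero map) `NA` is returned.
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param threshold FSC threshold; 0.143 for gold-standard half-map
#'   comparisons, 0.5 for map-vs-model.
#' @return resolution in Angstrom (`NA` if undefined).
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  cr <- curve$correlation
  fr <- curve$frequency
  ok <- !is.na(cr)
  if (!any(ok[-1])) return(NA_real_)
  for (i in seq(2, length(cr))) {
    if (is.na(cr[i])) next
    if (cr[i] < threshold) {
      # interpolate between previous defined shell and this one
      if (!any(ok[seq_len(i - 1)])) return(1 / fr[i])
      jprev <- max(which(ok[seq_len(i - 1)]))
      c0 <- cr[jprev]; c1 <- cr[i]
      if (c0 < threshold) return(1 / fr[jprev])
      t <- (c0 - threshold) / (c0 - c1)
      f <- fr[jprev] + t * (fr[i] - fr[jprev])
      return(1 / f)
    }
  }
  1 / fr[length(fr)] # never crossed: Nyquist
}

#' B-factor sharpening
#'
#' Multiplies Fourier amplitudes by `exp(+bfactor * k^2 / 4)`; negative
#' `bfactor` blurs, and `sharpen(sharpen(m, B), -B)` restores `m`.
#'
#' @param map a [density_map()].
#' @param bfactor B-factor in Angstrom^2 (positive sharpens).
#' @return a [density_map()].
#' @export
sharpen <- function(map, bfactor) {
  stopifnot(inherits(map, "density_map"), is.finite(bfactor))
  if (bfactor == 0) return(map)
  n <- box_size(map)
  k <- radius_grid_3d(n) / (n * map$apix)
  f <- fft_centered(map$values) * exp(bfactor * k^2 / 4)
  density_map(Re(ifft_centered(f)), map$apix)
}
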