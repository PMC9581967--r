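#' Wiener-weighted Fourier-slice reconstruction
#'
#' Inserts the (CTF-weighted) centred Fourier transforms of particle images
#' as central slices into a 2x-oversampled 3D grid and performs the Wiener
#' division `sum(CTF_i F_i) / (sum(CTF_i^2) + wiener)`, which also
#' compensates the slice sampling density. On complete noiseless CTF-free
#' data this inverts [project()] up to the interpolation band limit.
#'
#' @param images list of [image2d()] of equal size and pixel size.
#' @param pose_table data.frame of poses, one row per image (see [pose()]).
#' @param ctfs `NULL` (no CTF) or a list of [ctf_params()], one per image.
#' @param wiener Wiener regularization constant; the default `NULL` uses
#'   `0.1 * mean` of the accumulated squared-CTF weight over covered voxels.
#' @return a [density_map()] with the edge length of the input images.
#' @export
reconstruct <- function(images, pose_table, ctfs = NULL, wiener = NULL) {
  if (length(images) == 0L) stop("reconstruct: empty image list")
  check_poses(pose_table, length(images))
  if (!is.null(ctfs) && length(ctfs) != length(images))
    stop("reconstruct: need one ctf per image")
  n <- box_size(images[[1]])
  apix <- images[[1]]$apix
  for (im in images) {
    if (box_size(im) != n) stop("reconstruct: images differ in size")
    if (im$apix != apix) stop("reconstruct: images differ in pixel size")
  }
  m <- 2L * n
  acc <- array(complex(real = 0, imaginary = 0), dim = c(m, m, m))
  wt <- array(0, dim = c(m, m, m))
  dims <- as.integer(c(m, m, m))

  h <- freq_index(n)
  kx_idx <- rep(h, times = n)
  ky_idx <- rep(h, each = n)
  f <- h / n
  k_abs <- 1 / (n * apix) # physical frequency per index unit

  for (i in seq_along(images)) {
    p <- pose_table[i, , drop = FALSE]
    FI <- fft_centered(images[[i]]$values)
    # undo the pose shift so the particle is centred before insertion
    sx <- p$shift_x / apix
    sy <- p$shift_y / apix
    if (sx != 0 || sy != 0)
      FI <- FI * exp(2i * pi * outer(f * sx, f * sy, `+`))
    cvals <- if (is.null(ctfs)) 1 else
      ctf_evaluate(ctfs[[i]], kx_idx * k_abs, ky_idx * k_abs)
    R <- pose_matrix(p)
    q <- t(t(R) %*% rbind(2 * kx_idx, 2 * ky_idx, 0) + m / 2)
    cpp_trilinear_scatter(acc, wt, dims, q,
                          as.vector(FI) * cvals, rep_len(cvals^2, n * n))
    NULL
  }
  if (is.null(wiener)) wiener <- 0.1 * mean(wt[wt > 0])
  fhat <- acc / (wt + wiener)
  vol <- Re(ifft_centered(fhat))
  off <- n %/% 2L
  vol <- vol[off + seq_len(n), off + seq_len(n), off + seq_len(n)]
  corr <- gridding_correction_1d(n, m)
  density_map(vol / outer(outer(corr, corr), corr), apix)
}
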