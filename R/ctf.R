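#' Contrast transfer function parameters
#'
#' Standard phase-contrast CTF of a (possibly astigmatic) defocused electron
#' microscope. Sign convention: underfocus is positive defocus, and with the
#' returned contrast `CTF = -(sqrt(1 - A^2) sin(chi) + A cos(chi))` a point
#' scatterer (positive density) produces dark contrast at low frequency;
#' `ctf_evaluate` at k = 0 equals `-amplitude_contrast` exactly.
#'
#' @param defocus_u,defocus_v defocus along the major/minor astigmatism axes
#'   (Angstrom; underfocus positive).
#' @param astig_angle angle of the major axis (degrees).
#' @param voltage acceleration voltage (kV).
#' @param cs spherical aberration (mm).
#' @param amplitude_contrast amplitude-contrast fraction in \[0, 1\].
#' @param bfactor Gaussian envelope B-factor (Angstrom^2, >= 0).
#' @return an object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_u = 15000, defocus_v = defocus_u,
                       astig_angle = 0, voltage = 300, cs = 2.7,
                       amplitude_contrast = 0.07, bfactor = 0) {
  if (voltage <= 0) stop("ctf_params: voltage must be > 0")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("ctf_params: amplitude_contrast must be in [0, 1]")
  if (bfactor < 0) stop("ctf_params: bfactor must be >= 0")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast, bfactor = bfactor),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#'
#' @param voltage_kv acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v * (1 + v * 0.97845e-6))
}

#' Evaluate the CTF at spatial frequencies
#'
#' @param ctf a [ctf_params()] object.
#' @param kx,ky spatial frequency components (1/Angstrom); vectors of equal
#'   length (or arrays of equal shape).
#' @return contrast values, same shape as `kx`; in \[-1, 1\] before the
#'   B-factor envelope.
#' @examples
#' ctf_evaluate(ctf_params(amplitude_contrast = 0.1), 0, 0) # -0.1
#' @export
ctf_evaluate <- function(ctf, kx, ky) {
  stopifnot(inherits(ctf, "ctf_params"))
  if (!all(is.finite(kx)) || !all(is.finite(ky)))
    stop("ctf_evaluate: non-finite frequencies")
  lambda <- electron_wavelength(ctf$voltage)
  k2 <- kx^2 + ky^2
  # angle-dependent effective defocus
  ang <- atan2(ky, kx) - deg2rad(ctf$astig_angle)
  df <- 0.5 * (ctf$defocus_u + ctf$defocus_v +
                 (ctf$defocus_u - ctf$defocus_v) * cos(2 * ang))
  cs_a <- ctf$cs * 1e7 # mm -> Angstrom
  chi <- pi * lambda * df * k2 - pi / 2 * cs_a * lambda^3 * k2^2
  a <- ctf$amplitude_contrast
  base <- -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
  env <- exp(-ctf$bfactor * k2 / 4)
  out <- base * env
  if (!is.null(dim(kx))) dim(out) <- dim(kx)
  out
}

# CTF evaluated on the centred frequency grid of an n-px image.
ctf_image <- function(ctf, n, apix) {
  if (is.null(ctf)) return(matrix(1, n, n))
  k <- freq_index(n) / (n * apix)
  kx <- matrix(k, n, n)
  ky <- t(kx)
  ctf_evaluate(ctf, kx, ky)
}
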