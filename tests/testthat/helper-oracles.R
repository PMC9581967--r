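# Independent oracles and small fixtures shared across tests. These must not
# reuse the package's Fourier machinery for the operations they check.

# Real-space summed-ray projection: rotate sampling coordinates by t(R),
# trilinear-interpolate the volume, sum along z. Centred-origin convention
# (origin at n/2 + 1).
oracle_ray_project <- function(v, R, n) {
  cen <- n / 2 + 1
  g <- as.matrix(expand.grid(x = seq_len(n) - cen, y = seq_len(n) - cen))
  out <- matrix(0, n, n)
  v1 <- as.vector(v)
  id <- function(i, j, k) (k - 1) * n * n + (j - 1) * n + i
  for (z in seq_len(n) - cen) {
    q <- t(t(R) %*% t(cbind(g, z))) + cen
    i0 <- floor(q[, 1]); j0 <- floor(q[, 2]); k0 <- floor(q[, 3])
    fx <- q[, 1] - i0; fy <- q[, 2] - j0; fz <- q[, 3] - k0
    ok <- i0 >= 1 & j0 >= 1 & k0 >= 1 & i0 + 1 <= n & j0 + 1 <= n & k0 + 1 <= n
    val <- numeric(nrow(q))
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
      w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
        (if (dk) fz else 1 - fz)
      val[ok] <- val[ok] + v1[id(i0[ok] + di, j0[ok] + dj, k0[ok] + dk)] * w[ok]
    }
    out <- out + matrix(val, n, n)
  }
  out
}

# Compact random pseudo-atom phantom that fits well inside the box.
random_phantom <- function(n = 32, apix = 2, n_atoms = 6, seed = 42) {
  un <- withr::with_seed(seed, asym_unit_model(data.frame(
    x = runif(n_atoms, -8, 8), y = runif(n_atoms, -8, 8),
    z = runif(n_atoms, -8, 8),
    weight = runif(n_atoms, 0.5, 1.5), width = runif(n_atoms, 2, 4))))
  render_volume(un, list(list(R = diag(3), t = c(0, 0, 0))), n, apix)
}

# Small helical test model (radius scaled down from the demonstration model
# so it fits a 32-48 px box at 4 A/px).
mini_lattice <- function() helical_lattice(rise = 12, twist = -50, radius = 40)

mini_unit <- function() {
  half <- data.frame(x = c(-6, 4, 7), y = c(3, 5, -2), z = c(4, 2, 1),
                     weight = c(1.1, 1, 0.9), width = 3)
  asym_unit_model(rbind(half, transform(half, y = -y, z = -z)))
}

# Values representable exactly in float32 (MRC mode 2 round trips).
quantize_f32 <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  rw <- rawConnectionValue(con)
  close(con)
  con2 <- rawConnection(rw)
  v <- readBin(con2, "numeric", n = length(x), size = 4, endian = "little")
  close(con2)
  array(v, dim = dim(x) %||% length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drawn Gaussian ridge micrograph for tracer tests (independent of the
# package's filament simulator).
draw_ridge <- function(n, path_y, noise = 0.01, seed = 1, sigma = 8) {
  img <- matrix(0, n, n)
  xs <- seq(30, n - 30, by = 0.5)
  ys <- path_y(xs)
  for (i in seq_along(xs)) {
    ix <- round(xs[i]) + (-18:18); iy <- round(ys[i]) + (-18:18)
    ok <- ix >= 1 & ix <= n; ok2 <- iy >= 1 & iy <= n
    dd <- outer((ix[ok] - xs[i])^2, (iy[ok2] - ys[i])^2, `+`)
    img[ix[ok], iy[ok2]] <- pmax(img[ix[ok], iy[ok2]], exp(-dd / (2 * sigma^2)))
  }
  withr::with_seed(seed, img + matrix(rnorm(n * n, 0, noise), n, n))
}

# Uniformly-ish distributed random poses.
random_poses <- function(m, seed = 1) {
  withr::with_seed(seed, data.frame(
    rot = runif(m, 0, 360), tilt = acos(runif(m, -1, 1)) * 180 / pi,
    psi = runif(m, 0, 360), shift_x = 0, shift_y = 0))
}
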