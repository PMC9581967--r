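#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation kernels used for central-slice extraction and
// slice insertion on (oversampled) Fourier grids. Coordinates are 0-based
// fractional array indices; points whose 8-neighbour cube is not fully
// inside the grid contribute/return zero.

// [[Rcpp::export]]
ComplexVector cpp_trilinear_gather(ComplexVector vol, IntegerVector dim,
                                   NumericMatrix coords) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int n = coords.nrow();
  ComplexVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    Rcomplex acc; acc.r = 0.0; acc.i = 0.0;
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= n1 || j0 + 1 >= n2 || k0 + 1 >= n3) {
      out[p] = acc;
      continue;
    }
    double fx = x - i0, fy = y - j0, fz = z - k0;
    for (int dk = 0; dk < 2; ++dk) {
      double wz = dk ? fz : 1.0 - fz;
      for (int dj = 0; dj < 2; ++dj) {
        double wyz = (dj ? fy : 1.0 - fy) * wz;
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1.0 - fx) * wyz;
          const Rcomplex v = vol[(R_xlen_t)(i0 + di) +
                                 (R_xlen_t)n1 * ((j0 + dj) + (R_xlen_t)n2 * (k0 + dk))];
          acc.r += w * v.r;
          acc.i += w * v.i;
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// Scatter-add complex values (and squared-CTF weights) into an accumulation
// grid. Modifies acc and wt in place; both must be freshly allocated by the
// caller (no ALTREP sharing).

// [[Rcpp::export]]
void cpp_trilinear_scatter(ComplexVector acc, NumericVector wt, IntegerVector dim,
                           NumericMatrix coords, ComplexVector vals,
                           NumericVector w2) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int n = coords.nrow();
  for (int p = 0; p < n; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= n1 || j0 + 1 >= n2 || k0 + 1 >= n3)
      continue;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    const Rcomplex v = vals[p];
    const double wq = w2[p];
    for (int dk = 0; dk < 2; ++dk) {
      double wz = dk ? fz : 1.0 - fz;
      for (int dj = 0; dj < 2; ++dj) {
        double wyz = (dj ? fy : 1.0 - fy) * wz;
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1.0 - fx) * wyz;
          R_xlen_t idx = (R_xlen_t)(i0 + di) +
                         (R_xlen_t)n1 * ((j0 + dj) + (R_xlen_t)n2 * (k0 + dk));
          acc[idx].r += w * v.r;
          acc[idx].i += w * v.i;
          wt[idx] += w * wq;
        }
      }
    }
  }
}
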