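#include <Rcpp.h>
using namespace Rcpp;

// Accumulate, over atoms and periodic images, a tabulated radial profile
// onto an orthorhombic grid.  Voxel (i,j,k) of an (nx,ny,nz) grid sits at
// Cartesian (i*a/nx, j*b/ny, k*c/nz).  `profiles` holds one radial profile
// per element (rows: radius samples at spacing dr starting at 0); values
// beyond the table are treated as zero.  `images` is an n_img x 3 matrix of
// Cartesian lattice translations; `weights` carries per-atom weights
// (presence / n_frames).
// [[Rcpp::export]]
NumericVector direct_sum_kernel(NumericMatrix atom_xyz,
                                IntegerVector elem_idx,
                                NumericVector weights,
                                NumericMatrix profiles,
                                double dr,
                                NumericVector cell_len,
                                IntegerVector dims,
                                NumericMatrix images) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int natom = atom_xyz.nrow();
  const int nimg = images.nrow();
  const int nr = profiles.nrow();
  const double rmax = (nr - 1) * dr;
  NumericVector out(nx * ny * nz);
  std::vector<double> dx2(nx), dy2(ny), dz2(nz);
  const double sx = cell_len[0] / nx, sy = cell_len[1] / ny,
               sz = cell_len[2] / nz;
  for (int a = 0; a < natom; ++a) {
    const double w = weights[a];
    if (w == 0.0) continue;
    const double *prof = &profiles(0, elem_idx[a]);
    for (int g = 0; g < nimg; ++g) {
      const double tx = atom_xyz(a, 0) + images(g, 0);
      const double ty = atom_xyz(a, 1) + images(g, 1);
      const double tz = atom_xyz(a, 2) + images(g, 2);
      for (int i = 0; i < nx; ++i) { double d = i * sx - tx; dx2[i] = d * d; }
      for (int j = 0; j < ny; ++j) { double d = j * sy - ty; dy2[j] = d * d; }
      for (int k = 0; k < nz; ++k) { double d = k * sz - tz; dz2[k] = d * d; }
      double *o = REAL(out);
      for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
          const double dyz = dy2[j] + dz2[k];
          const std::ptrdiff_t base = (std::ptrdiff_t)(k * ny + j) * nx;
          for (int i = 0; i < nx; ++i) {
            const double r = std::sqrt(dx2[i] + dyz);
            if (r >= rmax) continue;
            const double u = r / dr;
            const int i0 = (int)u;
            const double f = u - i0;
            o[base + i] += w * (prof[i0] * (1.0 - f) + prof[i0 + 1] * f);
          }
        }
      }
    }
  }
  return out;
}

// Direct (non-FFT) Fourier synthesis of a Friedel half-set of reflections
// onto the grid: out[i,j,k] = sum_r 2*Re( G_r * exp(-2 pi i (h i/nx + k j/ny
// + l k/nz)) ).  The half-set must exclude (0,0,0) or count it once; here
// every listed reflection is doubled (band-edge shells never contain the
// origin).
// [[Rcpp::export]]
NumericVector shell_sum_kernel(NumericVector Gre, NumericVector Gim,
                               IntegerMatrix hkl, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nref = hkl.nrow();
  NumericVector out(nx * ny * nz);
  std::vector<double> axr(nx), axi(nx), ayr(ny), ayi(ny), azr(nz), azi(nz);
  double *o = REAL(out);
  const double twopi = 2.0 * M_PI;
  for (int r = 0; r < nref; ++r) {
    const double gr = Gre[r], gi = Gim[r];
    const int h = hkl(r, 0), k = hkl(r, 1), l = hkl(r, 2);
    for (int i = 0; i < nx; ++i) {
      double a = -twopi * h * i / nx; axr[i] = std::cos(a); axi[i] = std::sin(a);
    }
    for (int j = 0; j < ny; ++j) {
      double a = -twopi * k * j / ny; ayr[j] = std::cos(a); ayi[j] = std::sin(a);
    }
    for (int m = 0; m < nz; ++m) {
      double a = -twopi * l * m / nz; azr[m] = std::cos(a); azi[m] = std::sin(a);
    }
    for (int m = 0; m < nz; ++m) {
      for (int j = 0; j < ny; ++j) {
        const double cr = ayr[j] * azr[m] - ayi[j] * azi[m];
        const double ci = ayr[j] * azi[m] + ayi[j] * azr[m];
        const double tr = 2.0 * (gr * cr - gi * ci);
        const double ti = 2.0 * (gr * ci + gi * cr);
        const std::ptrdiff_t base = (std::ptrdiff_t)(m * ny + j) * nx;
        for (int i = 0; i < nx; ++i)
          o[base + i] += tr * axr[i] - ti * axi[i];
      }
    }
  }
  return out;
}
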