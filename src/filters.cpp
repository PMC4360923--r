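#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// reflective index (edge-repeating): ... 2 1 | 1 2 3 ... n | n n-1 ...
// iterated so it stays valid even when the overhang exceeds the extent
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// pad a 3D array by r voxels per side with reflective boundaries
static std::vector<double> pad_reflect(const double *a,
                                       int nx, int ny, int nz, int r) {
  const int px = nx + 2 * r, py = ny + 2 * r, pz = nz + 2 * r;
  std::vector<double> p((size_t)px * py * pz);
  for (int k = 0; k < pz; ++k) {
    int sk = reflect_idx(k - r, nz);
    for (int j = 0; j < py; ++j) {
      int sj = reflect_idx(j - r, ny);
      const double *src = a + nx * (sj + (size_t)ny * sk);
      double *dst = p.data() + (size_t)px * (j + (size_t)py * k);
      for (int i = 0; i < px; ++i)
        dst[i] = src[reflect_idx(i - r, nx)];
    }
  }
  return p;
}

// Non-local means with a separate guidance image. Patch distances (hence the
// weights and the normalizing constant) are computed on `guide`; the averaged
// intensities come from `values`. Patches use reflective padding; the search
// window is clipped at volume borders with weight renormalization, so every
// output voxel is a convex combination of values inside its window. The
// centre voxel's weight uses its literal (zero) patch distance, exp(0) = 1.
//
// Implementation sweeps over search offsets: for each offset t the squared
// guide difference field is box-filtered with the separable Gaussian patch
// kernel, giving all patch distances d(i, i+t) at once; this is equivalent
// to the direct per-voxel patch scan but runs in O(patch_width) per voxel
// and offset instead of O(patch_width^3).
// [[Rcpp::export]]
NumericVector cpp_psnlm(NumericVector values, NumericVector guide,
                        IntegerVector dims, int patch_radius,
                        int search_radius, double h, NumericVector g1d) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int pr = patch_radius, sr = search_radius;
  const int pw = 2 * pr + 1;
  const double h2 = h * h;
  if ((int)g1d.size() != pw)
    stop("patch kernel must have length 2*patch_radius + 1");

  const int P = pr + sr;                  // guide padding
  std::vector<double> G = pad_reflect(REAL(guide), nx, ny, nz, P);
  const int gx = nx + 2 * P, gy = ny + 2 * P;
  const size_t gsy = (size_t)gx, gsz = (size_t)gx * gy;

  // working extents for the difference field (volume plus patch apron)
  const int ex = nx + 2 * pr, ey = ny + 2 * pr, ez = nz + 2 * pr;
  std::vector<double> E((size_t)ex * ey * ez);
  std::vector<double> B1((size_t)nx * ey * ez);
  std::vector<double> B2((size_t)nx * ny * ez);
  std::vector<double> D((size_t)nx * ny * nz);

  const size_t N = (size_t)nx * ny * nz;
  std::vector<double> acc(N, 0.0), Z(N, 0.0);
  const double *V = REAL(values);
  const double *g = REAL(g1d);

  for (int tz = -sr; tz <= sr; ++tz) {
    for (int ty = -sr; ty <= sr; ++ty) {
      for (int tx = -sr; tx <= sr; ++tx) {
        // E[i,j,k] = (G[y] - G[y+t])^2, y = (i+sr, j+sr, k+sr) in padded
        const long toff = tx + (long)gsy * ty + (long)gsz * tz;
        for (int k = 0; k < ez; ++k)
          for (int j = 0; j < ey; ++j) {
            const double *row = G.data() + (size_t)sr +
                gsy * (j + sr) + gsz * (k + sr);
            double *er = E.data() + (size_t)ex * (j + (size_t)ey * k);
            for (int i = 0; i < ex; ++i) {
              const double d = row[i] - row[i + toff];
              er[i] = d * d;
            }
          }
        // separable valid-mode correlation with the 1D patch kernel
        for (int k = 0; k < ez; ++k)
          for (int j = 0; j < ey; ++j) {
            const double *er = E.data() + (size_t)ex * (j + (size_t)ey * k);
            double *br = B1.data() + (size_t)nx * (j + (size_t)ey * k);
            for (int i = 0; i < nx; ++i) {
              double s = 0.0;
              for (int o = 0; o < pw; ++o) s += g[o] * er[i + o];
              br[i] = s;
            }
          }
        for (int k = 0; k < ez; ++k)
          for (int j = 0; j < ny; ++j) {
            const double *b0 = B1.data() + (size_t)nx * (size_t)ey * k;
            double *br = B2.data() + (size_t)nx * (j + (size_t)ny * k);
            for (int i = 0; i < nx; ++i) {
              double s = 0.0;
              for (int o = 0; o < pw; ++o)
                s += g[o] * b0[i + (size_t)nx * (j + o)];
              br[i] = s;
            }
          }
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j) {
            double *dr = D.data() + (size_t)nx * (j + (size_t)ny * k);
            const double *b0 = B2.data() + (size_t)nx * j;
            for (int i = 0; i < nx; ++i) {
              double s = 0.0;
              for (int o = 0; o < pw; ++o)
                s += g[o] * b0[i + (size_t)nx * (size_t)ny * (k + o)];
              dr[i] = s;
            }
          }
        // accumulate weights for voxels whose neighbour i+t is in bounds
        const int k0 = std::max(0, -tz), k1 = std::min(nz, nz - tz);
        const int j0 = std::max(0, -ty), j1 = std::min(ny, ny - ty);
        const int i0 = std::max(0, -tx), i1 = std::min(nx, nx - tx);
        const long voff = tx + (long)nx * ty + (long)nx * ny * tz;
        for (int k = k0; k < k1; ++k)
          for (int j = j0; j < j1; ++j) {
            const size_t base = (size_t)nx * (j + (size_t)ny * k);
            const double *dr = D.data() + base;
            const double *vr = V + base + voff;
            double *ar = acc.data() + base;
            double *zr = Z.data() + base;
            for (int i = i0; i < i1; ++i) {
              const double w = std::exp(-dr[i] / h2);
              zr[i] += w;
              ar[i] += w * vr[i];
            }
          }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = acc[i] / Z[i];
  return out;
}

// 3D median filter with an odd cubic window and reflective boundaries
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector a, IntegerVector dims, int window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = (window - 1) / 2;
  std::vector<double> P = pad_reflect(REAL(a), nx, ny, nz, r);
  const int px = nx + 2 * r, py = ny + 2 * r;
  const size_t sy = (size_t)px, sz = (size_t)px * py;
  const int nw = window * window * window;

  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> buf(nw);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int t = 0;
        for (int dk = -r; dk <= r; ++dk)
          for (int dj = -r; dj <= r; ++dj)
            for (int di = -r; di <= r; ++di)
              buf[t++] = P[(size_t)(i + r + di) + sy * (j + r + dj) +
                           sz * (k + r + dk)];
        std::nth_element(buf.begin(), buf.begin() + nw / 2, buf.end());
        out[i + nx * (j + (size_t)ny * k)] = buf[nw / 2];
      }
    }
  }
  return out;
}
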