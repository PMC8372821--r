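#include <Rcpp.h>
using namespace Rcpp;

// levels: column-major 3D integer grid, 0 outside the mask, 1..ng inside.

// Symmetric gray-level co-occurrence counts for one integer offset.
// A pair is counted iff both voxels are inside the mask; counted both ways.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, IntegerVector dims,
                              int ng, IntegerVector offset) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = offset[0], oy = offset[1], oz = offset[2];
  NumericMatrix M(ng, ng);
  for (int z = 0; z < nz; ++z) {
    int z2 = z + oz; if (z2 < 0 || z2 >= nz) continue;
    for (int y = 0; y < ny; ++y) {
      int y2 = y + oy; if (y2 < 0 || y2 >= ny) continue;
      for (int x = 0; x < nx; ++x) {
        int x2 = x + ox; if (x2 < 0 || x2 >= nx) continue;
        int a = levels[x + nx * (y + (R_xlen_t)ny * z)];
        if (a == 0) continue;
        int b = levels[x2 + nx * (y2 + (R_xlen_t)ny * z2)];
        if (b == 0) continue;
        M(a - 1, b - 1) += 1.0;
        M(b - 1, a - 1) += 1.0;
      }
    }
  }
  return M;
}

// Gray-level run-length counts along one direction. A run is a maximal
// sequence of equal-level in-mask voxels along the direction; entry (g, l)
// counts runs of level g with length l. max_len rows are trimmed in R.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerVector levels, IntegerVector dims,
                               int ng, IntegerVector direction, int max_len) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dx = direction[0], dy = direction[1], dz = direction[2];
  NumericMatrix M(ng, max_len);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int g = levels[x + nx * (y + (R_xlen_t)ny * z)];
        if (g == 0) continue;
        // run start: predecessor out of grid, out of mask, or different level
        int px = x - dx, py = y - dy, pz = z - dz;
        if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz) {
          int gp = levels[px + nx * (py + (R_xlen_t)ny * pz)];
          if (gp == g) continue;
        }
        int len = 1;
        int cx = x + dx, cy = y + dy, cz = z + dz;
        while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
               levels[cx + nx * (cy + (R_xlen_t)ny * cz)] == g) {
          ++len; cx += dx; cy += dy; cz += dz;
        }
        if (len > max_len) len = max_len;  // cannot occur when max_len >= max dim path
        M(g - 1, len - 1) += 1.0;
      }
    }
  }
  return M;
}

// Periodic (circular) correlation-style filtering along one axis of a 3D
// grid: y[i] = sum_k h[k] * x[(i + k) mod N] along `axis` (0, 1 or 2).
// [[Rcpp::export]]
NumericVector cpp_filter_axis(NumericVector x, IntegerVector dims,
                              NumericVector h, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int L = h.size();
  NumericVector out(x.size());
  const int n = dims[axis];
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int xx = 0; xx < nx; ++xx) {
        R_xlen_t base = xx + nx * (y + (R_xlen_t)ny * z);
        int pos = (axis == 0) ? xx : (axis == 1) ? y : z;
        R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nx : (R_xlen_t)nx * ny;
        double acc = 0.0;
        for (int k = 0; k < L; ++k) {
          int j = pos + k; j %= n;
          acc += h[k] * x[base + ((R_xlen_t)j - pos) * stride];
        }
        out[base] = acc;
      }
    }
  }
  return out;
}
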