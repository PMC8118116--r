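#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>
using namespace Rcpp;

// Parallel-beam ray transform with Joseph (interpolating) weights.
//
// Conventions (shared by forward, adjoint and FBP backprojector):
//   image: M rows x N cols, pixel (i, j) centred at
//     x = (j - (N-1)/2) * pix,  y = (i - (M-1)/2) * pix   (0-based i, j)
//   detector cell k centred at s = (k - (nd-1)/2) * ds
//   ray(theta, s) = { (x, y) : x*cos(theta) + y*sin(theta) = s }
//
// The ray is marched one pixel-row (or pixel-column) at a time along its
// dominant direction; the transverse coordinate is linearly interpolated
// between the two neighbouring pixels and each sample carries the path
// length pix / max(|cos|, |sin|) so entries are line integrals in value*mm.

// Shared kernel: accumulate == false -> forward projection (image fixed,
// sino written); accumulate == true -> adjoint (sino fixed, image written).
static void joseph_sweep(double* img, const double* sino_in, double* sino_out,
                         int M, int N, double pix,
                         const NumericVector& angles, int nd, double ds,
                         bool adjoint) {
  const int nv = angles.size();
  const double cy = (M - 1) / 2.0, cx = (N - 1) / 2.0, cs = (nd - 1) / 2.0;
  for (int t = 0; t < nv; ++t) {
    const double co = std::cos(angles[t]);
    const double si = std::sin(angles[t]);
    const bool row_march = std::fabs(co) >= std::fabs(si);
    const double wlen = pix / (row_march ? std::fabs(co) : std::fabs(si));
    for (int k = 0; k < nd; ++k) {
      const double s = (k - cs) * ds;
      const long sidx = (long)t + (long)nv * k;  // nv x nd column-major
      double acc = 0.0;
      const double sval = adjoint ? sino_in[sidx] * wlen : 0.0;
      if (adjoint && sval == 0.0) continue;
      if (row_march) {
        // cf(i) = slope * i + icpt; both-neighbour interior where
        // 0 <= floor(cf) and floor(cf)+1 <= N-1, i.e. 0 <= cf and cf <= N-1
        const double slope = -(si / co);
        const double icpt = (s + cy * pix * si) / co / pix + cx;
        int lo = 0, hi = M - 1;
        if (slope > 1e-300 || slope < -1e-300) {
          double t0 = (0.0 - icpt) / slope, t1 = ((double)N - 1.0 - icpt) / slope;
          if (t0 > t1) std::swap(t0, t1);
          lo = (int)std::ceil(std::min(std::max(t0, 0.0), (double)M));
          hi = (int)std::floor(std::max(std::min(t1, (double)(M - 1)), -2.0));
        } else if (icpt < 0.0 || icpt > N - 1.0) { lo = 1; hi = 0; }
        for (int i = lo; i <= hi; ++i) {
          const double cf = slope * i + icpt;
          int j0 = (int)cf;
          double w = cf - j0;
          if (j0 >= N - 1) { j0 = N - 2; w = 1.0; }  // cf == N-1 (safety clamp)
          if (j0 < 0) { j0 = 0; w = 0.0; }
          const long p = (long)i + (long)M * j0;
          if (adjoint) { img[p] += (1.0 - w) * sval; img[p + M] += w * sval; }
          else acc += (1.0 - w) * img[p] + w * img[p + M];
        }
        // fringe: samples with exactly one in-bounds neighbour
        for (int pass = 0; pass < 2; ++pass) {
          int i = (pass == 0) ? std::min(lo - 1, M - 1) : std::max(hi + 1, 0);
          if (pass == 1 && hi < lo - 1 && i <= std::min(lo - 1, M - 1) && lo - 1 >= 0) i = std::min(lo - 1, M - 1) + 1;
          for (; i >= 0 && i < M; i += (pass == 0) ? -1 : 1) {
            const double cf = slope * i + icpt;
            const int j0 = (int)std::floor(cf);
            const double w = cf - j0;
            bool any = false;
            if (j0 >= 0 && j0 < N) {
              const long p = (long)i + (long)M * j0;
              if (adjoint) img[p] += (1.0 - w) * sval; else acc += (1.0 - w) * img[p];
              any = true;
            }
            if (j0 + 1 >= 0 && j0 + 1 < N) {
              const long p = (long)i + (long)M * (j0 + 1);
              if (adjoint) img[p] += w * sval; else acc += w * img[p];
              any = true;
            }
            if (!any) break;  // moving away from the image
          }
        }
      } else {
        const double slope = -(co / si);
        const double icpt = (s + cx * pix * co) / si / pix + cy;
        int lo = 0, hi = N - 1;
        if (slope > 1e-300 || slope < -1e-300) {
          double t0 = (0.0 - icpt) / slope, t1 = ((double)M - 1.0 - icpt) / slope;
          if (t0 > t1) std::swap(t0, t1);
          lo = (int)std::ceil(std::min(std::max(t0, 0.0), (double)N));
          hi = (int)std::floor(std::max(std::min(t1, (double)(N - 1)), -2.0));
        } else if (icpt < 0.0 || icpt > M - 1.0) { lo = 1; hi = 0; }
        for (int j = lo; j <= hi; ++j) {
          const double rf = slope * j + icpt;
          int i0 = (int)rf;
          double w = rf - i0;
          if (i0 >= M - 1) { i0 = M - 2; w = 1.0; }
          if (i0 < 0) { i0 = 0; w = 0.0; }
          const long p = (long)i0 + (long)M * j;
          if (adjoint) { img[p] += (1.0 - w) * sval; img[p + 1] += w * sval; }
          else acc += (1.0 - w) * img[p] + w * img[p + 1];
        }
        for (int pass = 0; pass < 2; ++pass) {
          int j = (pass == 0) ? std::min(lo - 1, N - 1) : std::max(hi + 1, 0);
          if (pass == 1 && hi < lo - 1 && j <= std::min(lo - 1, N - 1) && lo - 1 >= 0) j = std::min(lo - 1, N - 1) + 1;
          for (; j >= 0 && j < N; j += (pass == 0) ? -1 : 1) {
            const double rf = slope * j + icpt;
            const int i0 = (int)std::floor(rf);
            const double w = rf - i0;
            bool any = false;
            if (i0 >= 0 && i0 < M) {
              const long p = (long)i0 + (long)M * j;
              if (adjoint) img[p] += (1.0 - w) * sval; else acc += (1.0 - w) * img[p];
              any = true;
            }
            if (i0 + 1 >= 0 && i0 + 1 < M) {
              const long p = (long)(i0 + 1) + (long)M * j;
              if (adjoint) img[p] += w * sval; else acc += w * img[p];
              any = true;
            }
            if (!any) break;
          }
        }
      }
      if (!adjoint) sino_out[sidx] = acc * wlen;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix image, double pix,
                                  NumericVector angles, int n_detectors,
                                  double detector_spacing) {
  NumericMatrix sino(angles.size(), n_detectors);
  joseph_sweep(REAL(image), nullptr, REAL(sino), image.nrow(), image.ncol(),
               pix, angles, n_detectors, detector_spacing, false);
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix sino, int M, int N, double pix,
                               NumericVector angles, double detector_spacing) {
  NumericMatrix img(M, N);
  joseph_sweep(REAL(img), REAL(sino), nullptr, M, N, pix, angles,
               sino.ncol(), detector_spacing, true);
  return img;
}

// Pixel-driven backprojection of a filtered sinogram (FBP second stage):
// for every pixel, interpolate each view's filtered profile at
// s = x cos + y sin and average with weight pi / n_views.
// [[Rcpp::export]]
NumericMatrix cpp_pixel_backproject(NumericMatrix fsino, int M, int N,
                                    double pix, NumericVector angles,
                                    double detector_spacing) {
  const int nv = angles.size(), nd = fsino.ncol();
  const double cy = (M - 1) / 2.0, cx = (N - 1) / 2.0, cs = (nd - 1) / 2.0;
  NumericMatrix img(M, N);
  const double dtheta = M_PI / nv;
  std::vector<double> cos_t(nv), sin_t(nv);
  for (int t = 0; t < nv; ++t) { cos_t[t] = std::cos(angles[t]); sin_t[t] = std::sin(angles[t]); }
  for (int j = 0; j < N; ++j) {
    const double x = (j - cx) * pix;
    for (int i = 0; i < M; ++i) {
      const double y = (i - cy) * pix;
      double acc = 0.0;
      for (int t = 0; t < nv; ++t) {
        const double df = (x * cos_t[t] + y * sin_t[t]) / detector_spacing + cs;
        const int k0 = (int)std::floor(df);
        const double w = df - k0;
        if (k0 >= 0 && k0 < nd) acc += (1.0 - w) * fsino(t, k0);
        if (k0 + 1 >= 0 && k0 + 1 < nd) acc += w * fsino(t, k0 + 1);
      }
      img(i, j) = acc * dtheta;
    }
  }
  return img;
}

// Union-find over voxels: edges along x, y, z where the auxiliary gradient
// support is OFF merge their endpoints; used to project a half-quadratic
// iterate onto the exactly piecewise-constant volume implied by its support.
// merge_*: logical arrays (length = prod(dims)); an entry at position p is
// only consulted when the forward neighbour along that axis exists.
// Returns 1-based component labels.
// [[Rcpp::export]]
IntegerVector cpp_flat_components(LogicalVector merge_x, LogicalVector merge_y,
                                  LogicalVector merge_z, IntegerVector dims) {
  const int M = dims[0], N = dims[1], C = dims[2];
  const long n = (long)M * N * C;
  std::vector<long> parent(n);
  for (long p = 0; p < n; ++p) parent[p] = p;
  std::function<long(long)> find = [&](long p) {
    while (parent[p] != p) { parent[p] = parent[parent[p]]; p = parent[p]; }
    return p;
  };
  auto unite = [&](long a, long b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < M; ++i) {
        const long p = (long)i + (long)M * j + (long)M * N * c;
        if (i + 1 < M && merge_y[p]) unite(p, p + 1);
        if (j + 1 < N && merge_x[p]) unite(p, p + M);
        if (c + 1 < C && merge_z[p]) unite(p, p + (long)M * N);
      }
  IntegerVector lab(n);
  std::vector<long> relab(n, 0);
  long next = 0;
  for (long p = 0; p < n; ++p) {
    long r = find(p);
    if (relab[r] == 0) relab[r] = ++next;
    lab[p] = (int)relab[r];
  }
  return lab;
}
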