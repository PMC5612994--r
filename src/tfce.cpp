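#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Threshold-free cluster enhancement on a 3D image.
// For each voxel v: TFCE(v) = sum over thresholds t = dh, 2*dh, ... <= img[v]
// of extent(t, v)^e * t^h * dh, where extent(t, v) is the size of the
// suprathreshold (img >= t) connected component containing v.
// Non-finite and non-positive voxels contribute nothing and never join a
// component. Connectivity: 6 (faces), 18 (+edges) or 26 (+corners).
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector img, IntegerVector dims,
                       double e_param, double h_param, double dh,
                       int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  if (img.size() != nvox) stop("image length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<double> val(nvox);
  double max_h = 0.0;
  for (int i = 0; i < nvox; ++i) {
    double v = img[i];
    if (!std::isfinite(v) || v < 0.0) v = 0.0;
    val[i] = v;
    if (v > max_h) max_h = v;
  }
  NumericVector out(nvox, 0.0);
  if (max_h <= 0.0) return out;
  if (dh <= 0.0) dh = max_h / 100.0;

  // neighbor offsets
  std::vector<int> dxs, dys, dzs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int n_off = (int)dxs.size();

  std::vector<int> comp(nvox), stack, members;
  for (double thr = dh; thr <= max_h + 1e-12; thr += dh) {
    std::fill(comp.begin(), comp.end(), -1);
    for (int seed = 0; seed < nvox; ++seed) {
      if (val[seed] < thr || comp[seed] >= 0) continue;
      // flood fill one component
      members.clear();
      stack.clear();
      stack.push_back(seed);
      comp[seed] = seed;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        members.push_back(cur);
        const int z = cur / (nx * ny), rem = cur % (nx * ny);
        const int y = rem / nx, x = rem % nx;
        for (int o = 0; o < n_off; ++o) {
          const int xx = x + dxs[o], yy = y + dys[o], zz = z + dzs[o];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          const int nb = xx + nx * (yy + ny * zz);
          if (val[nb] >= thr && comp[nb] < 0) {
            comp[nb] = seed;
            stack.push_back(nb);
          }
        }
      }
      const double add =
          std::pow((double)members.size(), e_param) * std::pow(thr, h_param) * dh;
      for (size_t i = 0; i < members.size(); ++i) out[members[i]] += add;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
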