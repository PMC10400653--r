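// Hot kernel of the snowballing parcellation: connected-component labelling
// of a suprathreshold voxel set and per-cluster local-maximum extraction
// with minimum-separation pruning. Works on full-lattice linear indices.
#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".cluster_peaks_cpp")]]
IntegerVector cluster_peaks_cpp(IntegerVector supra1, NumericVector vals,
                                IntegerVector dims, IntegerMatrix offs,
                                int min_cluster, double peak_sep_mm,
                                NumericVector voxel_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const int noff = offs.nrow();
  std::vector<int> lab(ntot, -1);          // -1 background, 0 unlabelled supra
  std::vector<int> supra(supra1.size());
  for (int i = 0; i < supra1.size(); ++i) {
    supra[i] = supra1[i] - 1;              // to 0-based
    lab[supra[i]] = 0;
  }
  std::sort(supra.begin(), supra.end());

  int nlab = 0;
  std::vector<int> comp_of(supra.size());
  std::vector<std::vector<int>> members;
  for (size_t s = 0; s < supra.size(); ++s) {
    if (lab[supra[s]] != 0) continue;
    ++nlab;
    members.push_back(std::vector<int>());
    std::queue<int> q;
    q.push(supra[s]);
    lab[supra[s]] = nlab;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      members.back().push_back(cur);
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
      for (int o = 0; o < noff; ++o) {
        int i = ci + offs(o, 0), j = cj + offs(o, 1), k = ck + offs(o, 2);
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
        int nb = i + nx * (j + (R_xlen_t)ny * k);
        if (lab[nb] == 0) { lab[nb] = nlab; q.push(nb); }
      }
    }
  }

  std::vector<int> peaks;
  for (int c = 0; c < nlab; ++c) {
    std::vector<int> &mem = members[c];
    if ((int)mem.size() < min_cluster) continue;
    std::vector<int> mx;
    for (int cur : mem) {
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
      bool is_max = true;
      for (int o = 0; o < noff && is_max; ++o) {
        int i = ci + offs(o, 0), j = cj + offs(o, 1), k = ck + offs(o, 2);
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
        int nb = i + nx * (j + (R_xlen_t)ny * k);
        if (lab[nb] != c + 1) continue;
        if (vals[nb] > vals[cur] || (vals[nb] == vals[cur] && nb < cur))
          is_max = false;
      }
      if (is_max) mx.push_back(cur);
    }
    // order by decreasing value, ties by lowest index; greedy separation
    std::sort(mx.begin(), mx.end(), [&](int a, int b) {
      if (vals[a] != vals[b]) return vals[a] > vals[b];
      return a < b;
    });
    if (peak_sep_mm > 0 && mx.size() > 1) {
      std::vector<int> kept;
      double sep2 = peak_sep_mm * peak_sep_mm;
      for (int cand : mx) {
        double cx = (cand % nx) * voxel_mm[0];
        double cy = ((cand / nx) % ny) * voxel_mm[1];
        double cz = (cand / (nx * ny)) * voxel_mm[2];
        bool ok = true;
        for (int kc : kept) {
          double dx = cx - (kc % nx) * voxel_mm[0];
          double dy = cy - ((kc / nx) % ny) * voxel_mm[1];
          double dz = cz - (kc / (nx * ny)) * voxel_mm[2];
          if (dx * dx + dy * dy + dz * dz < sep2) { ok = false; break; }
        }
        if (ok) kept.push_back(cand);
      }
      mx = kept;
    }
    for (int m : mx) peaks.push_back(m + 1);   // back to 1-based
  }
  std::sort(peaks.begin(), peaks.end());
  return wrap(peaks);
}
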