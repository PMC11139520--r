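#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Voxel linear order: i = iz + nz * (iy + ny * ix), 0-based.

static inline void neighbor_offsets(int connectivity,
                                    std::vector<std::array<int, 3>>& off) {
  off.clear();
  for (int kx = -1; kx <= 1; ++kx)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kz = -1; kz <= 1; ++kz) {
        if (kx == 0 && ky == 0 && kz == 0) continue;
        int manh = std::abs(kx) + std::abs(ky) + std::abs(kz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({kz, ky, kx});
      }
}

// Connected components of a logical volume.  Components are labelled 1..K in
// order of their minimum linear index (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector fg, int nz, int ny, int nx,
                                   int connectivity) {
  R_xlen_t N = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(N, 0);
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(connectivity, off);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (!fg[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int iz = (int)(cur % nz);
      int iy = (int)((cur / nz) % ny);
      int ix = (int)(cur / ((R_xlen_t)nz * ny));
      for (const auto& o : off) {
        int zz = iz + o[0], yy = iy + o[1], xx = ix + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (fg[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

struct WsEntry {
  double height;   // distance value: larger floods first
  unsigned long order;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.height != b.height) return a.height < b.height;  // max-heap on height
    return a.order > b.order;                              // FIFO among equal
  }
};

// Marker-controlled watershed on the *negated* distance map: basins grow from
// seed markers downhill in distance, restricted to the foreground mask.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector dist, IntegerVector seeds,
                            LogicalVector fg, int nz, int ny, int nx,
                            int connectivity) {
  R_xlen_t N = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(N, 0);
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(connectivity, off);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  unsigned long order = 0;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (seeds[i] > 0) {
      lab[i] = seeds[i];
      pq.push({dist[i], order++, i});
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    R_xlen_t cur = e.idx;
    int curlab = lab[cur];
    int iz = (int)(cur % nz);
    int iy = (int)((cur / nz) % ny);
    int ix = (int)(cur / ((R_xlen_t)nz * ny));
    for (const auto& o : off) {
      int zz = iz + o[0], yy = iy + o[1], xx = ix + o[2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!fg[j] || lab[j] != 0) continue;
      lab[j] = curlab;
      pq.push({dist[j], order++, j});
    }
  }
  return lab;
}
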