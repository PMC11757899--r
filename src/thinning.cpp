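// Deterministic 3D thinning and voxel topology utilities.
//
// Thinning peels border voxels in six directional subiterations; a voxel is
// removed only if it is a simple point (removal preserves topology under the
// standard 26-adjacency foreground / 6-adjacency background convention,
// characterised locally after Malandain & Bertrand) and not a curve endpoint.
// Within a subiteration voxels are re-tested sequentially in a fixed
// ascending scan order, so the result is bit-identical across runs.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbourhood index i in [0,27): offsets iz = i%3-1, iy = (i/3)%3-1,
// ix = i/9-1; the centre voxel is i == 13.
static bool is_simple_point(const bool nb[27]) {
  // exactly one 26-connected foreground component among the 26 neighbours
  bool vis[27] = {false};
  int comp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || vis[i]) continue;
    ++comp;
    if (comp > 1) return false;
    std::vector<int> st(1, i);
    vis[i] = true;
    while (!st.empty()) {
      const int j = st.back(); st.pop_back();
      const int jz = j % 3 - 1, jy = (j / 3) % 3 - 1, jx = j / 9 - 1;
      for (int m = 0; m < 27; ++m) {
        if (m == 13 || vis[m] || !nb[m]) continue;
        const int mz = m % 3 - 1, my = (m / 3) % 3 - 1, mx = m / 9 - 1;
        if (std::abs(mz - jz) <= 1 && std::abs(my - jy) <= 1 &&
            std::abs(mx - jx) <= 1) {
          vis[m] = true;
          st.push_back(m);
        }
      }
    }
  }
  if (comp != 1) return false;
  // exactly one 6-connected background component in the 18-neighbourhood
  // that touches a face neighbour
  bool vis2[27] = {false};
  int comp2 = 0;
  for (int i = 0; i < 27; ++i) {
    const int iz = i % 3 - 1, iy = (i / 3) % 3 - 1, ix = i / 9 - 1;
    const int r = iz * iz + iy * iy + ix * ix;
    if (i == 13 || r != 1 || nb[i] || vis2[i]) continue;  // seed: bg face nbr
    ++comp2;
    if (comp2 > 1) return false;
    std::vector<int> st(1, i);
    vis2[i] = true;
    while (!st.empty()) {
      const int j = st.back(); st.pop_back();
      const int jz = j % 3 - 1, jy = (j / 3) % 3 - 1, jx = j / 9 - 1;
      for (int m = 0; m < 27; ++m) {
        if (m == 13 || vis2[m] || nb[m]) continue;
        const int mz = m % 3 - 1, my = (m / 3) % 3 - 1, mx = m / 9 - 1;
        if (mz * mz + my * my + mx * mx > 2) continue;  // stay in 18-nbhd
        if (std::abs(mz - jz) + std::abs(my - jy) + std::abs(mx - jx) == 1) {
          vis2[m] = true;
          st.push_back(m);
        }
      }
    }
  }
  return comp2 == 1;
}

// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const size_t N = (size_t)D * H * W;
  std::vector<unsigned char> v(N);
  for (size_t i = 0; i < N; ++i) v[i] = mask[i] != 0;
  auto at = [&](int d, int h, int w) -> unsigned char {
    if (d < 0 || d >= D || h < 0 || h >= H || w < 0 || w >= W) return 0;
    return v[d + (size_t)D * (h + (size_t)H * w)];
  };
  static const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                                 {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<size_t> cand;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          for (int d = 0; d < D; ++d) {
            const size_t n = d + (size_t)D * (h + (size_t)H * w);
            if (!v[n]) continue;
            if (at(d + dirs[dir][0], h + dirs[dir][1], w + dirs[dir][2]))
              continue;
            cand.push_back(n);
          }
      for (size_t n : cand) {
        if (!v[n]) continue;
        const int d = (int)(n % D);
        const int h = (int)((n / D) % H);
        const int w = (int)(n / ((size_t)D * H));
        bool nb[27];
        int fg = 0;
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              const bool f = at(d + oz, h + oy, w + ox) != 0;
              nb[(oz + 1) + 3 * (oy + 1) + 9 * (ox + 1)] = f;
              if (f && !(oz == 0 && oy == 0 && ox == 0)) ++fg;
            }
        if (fg <= 1) continue;  // curve endpoint (or isolated voxel): keep
        if (is_simple_point(nb)) {
          v[n] = 0;
          changed = true;
        }
      }
    }
  }
  IntegerVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = v[i];
  out.attr("dim") = dims;
  return out;
}

// Connected-component labelling of a binary volume; connectivity 6 or 26.
// Labels are assigned in ascending scan order of each component's first
// voxel, so labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const size_t N = (size_t)D * H * W;
  IntegerVector lab(N);
  lab.attr("dim") = dims;
  std::vector<int> offs;
  for (int ox = -1; ox <= 1; ++ox)
    for (int oy = -1; oy <= 1; ++oy)
      for (int oz = -1; oz <= 1; ++oz) {
        if (!ox && !oy && !oz) continue;
        const int man = std::abs(ox) + std::abs(oy) + std::abs(oz);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back(oz);
        offs.push_back(oy);
        offs.push_back(ox);
      }
  int next = 0;
  std::vector<size_t> st;
  for (size_t n = 0; n < N; ++n) {
    if (!mask[n] || lab[n]) continue;
    ++next;
    lab[n] = next;
    st.assign(1, n);
    while (!st.empty()) {
      const size_t j = st.back(); st.pop_back();
      const int d = (int)(j % D), h = (int)((j / D) % H),
                w = (int)(j / ((size_t)D * H));
      for (size_t o = 0; o < offs.size(); o += 3) {
        const int dd = d + offs[o], hh = h + offs[o + 1], ww = w + offs[o + 2];
        if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
          continue;
        const size_t m = dd + (size_t)D * (hh + (size_t)H * ww);
        if (mask[m] && !lab[m]) {
          lab[m] = next;
          st.push_back(m);
        }
      }
    }
  }
  return lab;
}

// Number of foreground 26-neighbours of every voxel.
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(IntegerVector mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const size_t N = (size_t)D * H * W;
  IntegerVector cnt(N);
  cnt.attr("dim") = dims;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const size_t n = d + (size_t)D * (h + (size_t)H * w);
        if (!mask[n]) continue;
        int c = 0;
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              if (!ox && !oy && !oz) continue;
              const int dd = d + oz, hh = h + oy, ww = w + ox;
              if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
                continue;
              if (mask[dd + (size_t)D * (hh + (size_t)H * ww)]) ++c;
            }
        cnt[n] = c;
      }
  return cnt;
}
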