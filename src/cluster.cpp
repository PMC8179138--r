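// Greedy density clustering of water observations into hydration sites, and
// brute-force nearest-neighbour queries for the entropy estimators.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline long long cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices
  const long long B = 1 << 20;
  return (((long long)(ix + B)) << 42) | (((long long)(iy + B)) << 21) | (long long)(iz + B);
}

// Count ties are broken by lexicographically smallest (x, y, z) coordinate,
// which is deterministic AND invariant to permuting the input rows (a
// row-order tie-break would make the site centers depend on frame order).
// [[Rcpp::export]]
List greedy_cluster_cpp(NumericMatrix pts, IntegerVector frame_id, int n_frames,
                        double radius, double min_occupancy) {
  const int n = pts.nrow();
  const double r2 = radius * radius;
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2); }

  // cell list (cell edge = radius)
  std::unordered_map<long long, int> cell_idx; // key -> index into cells
  std::vector<std::vector<int>> cells;
  std::vector<int> cell_of(n);
  cell_idx.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    long long key = cell_key((int)std::floor(X[i] / radius),
                             (int)std::floor(Y[i] / radius),
                             (int)std::floor(Z[i] / radius));
    auto it = cell_idx.find(key);
    int c;
    if (it == cell_idx.end()) {
      c = (int)cells.size();
      cell_idx.emplace(key, c);
      cells.push_back(std::vector<int>());
    } else c = it->second;
    cells[c].push_back(i);
    cell_of[i] = c;
  }
  // neighbour cell indices (incl. self) per cell
  std::vector<std::vector<int>> cell_nb(cells.size());
  for (auto& kv : cell_idx) {
    long long key = kv.first;
    const long long B = 1 << 20;
    int ix = (int)((key >> 42) & 0x1FFFFF) - B;
    int iy = (int)((key >> 21) & 0x1FFFFF) - B;
    int iz = (int)(key & 0x1FFFFF) - B;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cell_idx.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it != cell_idx.end()) cell_nb[kv.second].push_back(it->second);
        }
  }

  std::vector<bool> used(n, false);
  std::vector<int> count(n, 1); // includes self

  // initial counts via symmetric pair enumeration
  for (size_t c = 0; c < cells.size(); ++c) {
    for (int cn : cell_nb[c]) {
      if (cn < (int)c) continue; // each cell pair once
      const std::vector<int>& A = cells[c];
      const std::vector<int>& Bv = cells[cn];
      if (cn == (int)c) {
        for (size_t a = 0; a + 1 < A.size(); ++a)
          for (size_t b = a + 1; b < A.size(); ++b) {
            int i = A[a], j = A[b];
            double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
            if (dx * dx + dy * dy + dz * dz <= r2) { ++count[i]; ++count[j]; }
          }
      } else {
        for (int i : A) for (int j : Bv) {
          double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
          if (dx * dx + dy * dy + dz * dz <= r2) { ++count[i]; ++count[j]; }
        }
      }
    }
  }

  std::vector<double> cx, cy, cz, occ;
  std::vector<int> nclaim;
  IntegerVector assign(n, 0);
  std::vector<char> frame_seen(n_frames, 0);
  std::vector<int> claimed;

  auto coordLess = [&](int i, int j) {
    if (X[i] != X[j]) return X[i] < X[j];
    if (Y[i] != Y[j]) return Y[i] < Y[j];
    return Z[i] < Z[j];
  };

  for (int site = 1;; ++site) {
    int best = -1, bestc = 0;
    for (int i = 0; i < n; ++i) {
      if (used[i]) continue;
      if (count[i] > bestc || (count[i] == bestc && best >= 0 && coordLess(i, best))) {
        bestc = count[i]; best = i;
      }
    }
    if (best < 0) break;
    // claim everything within radius of the best point
    claimed.clear();
    for (int cn : cell_nb[cell_of[best]])
      for (int j : cells[cn]) {
        if (used[j]) continue;
        double dx = X[best] - X[j], dy = Y[best] - Y[j], dz = Z[best] - Z[j];
        if (dx * dx + dy * dy + dz * dz <= r2) claimed.push_back(j);
      }
    std::fill(frame_seen.begin(), frame_seen.end(), 0);
    int nfr = 0;
    for (int j : claimed) if (!frame_seen[frame_id[j]]) { frame_seen[frame_id[j]] = 1; ++nfr; }
    double occupancy = (double)nfr / n_frames;
    if (occupancy < min_occupancy) break;
    cx.push_back(X[best]); cy.push_back(Y[best]); cz.push_back(Z[best]);
    occ.push_back(occupancy); nclaim.push_back((int)claimed.size());
    for (int j : claimed) { used[j] = true; assign[j] = site; }
    // decrement counts of surviving points near the removed ones
    for (int j : claimed)
      for (int cn : cell_nb[cell_of[j]])
        for (int z : cells[cn]) {
          if (used[z]) continue;
          double dx = X[j] - X[z], dy = Y[j] - Y[z], dz = Z[j] - Z[z];
          if (dx * dx + dy * dy + dz * dz <= r2) --count[z];
        }
  }

  return List::create(
    _["x"] = cx, _["y"] = cy, _["z"] = cz,
    _["occupancy"] = occ, _["n_claimed"] = nclaim, _["assignment"] = assign);
}

// Euclidean nearest-neighbour distance for each row of pts.
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericMatrix pts) {
  const int n = pts.nrow(), d = pts.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0;
      for (int k = 0; k < d; ++k) { double t = pts(i, k) - pts(j, k); s += t * t; }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Geodesic (great-circle) nearest-neighbour angle for unit vectors.
// [[Rcpp::export]]
NumericVector nn_angle_cpp(NumericMatrix u) {
  const int n = u.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = -1.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dot = u(i, 0) * u(j, 0) + u(i, 1) * u(j, 1) + u(i, 2) * u(j, 2);
      if (dot > best) best = dot;
    }
    if (best > 1.0) best = 1.0;
    if (best < -1.0) best = -1.0;
    out[i] = std::acos(best);
  }
  return out;
}
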