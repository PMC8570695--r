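#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Rasterised 2D power diagram: pixel (r, c) is assigned to the seed j
// minimising d2(pixel, seed_j) - w_j. Squared distances are supplied
// per-axis (Dx: n_cols x n_seeds, Dy: n_rows x n_seeds) so periodic
// wrap-around is handled by the caller when building Dx/Dy.

// Tile-local candidate lists: a 16x16 pixel tile only competes among
// seeds within a generous radius of the tile centre, cutting the per-
// iteration cost by an order of magnitude on large layers. The radius
// (5 mean cell diameters plus the tile diagonal) is far beyond any
// plausible boundary shift of the weight iteration; an empty list falls
// back to the full seed set.
struct TileCandidates {
  int tile, ntx, nty;
  std::vector<std::vector<int> > cand;
  TileCandidates(const NumericMatrix& Dx, const NumericMatrix& Dy,
                 double rad2) {
    const int nr = Dy.nrow(), nc = Dx.nrow(), n = Dx.ncol();
    tile = 16;
    ntx = (nc + tile - 1) / tile;
    nty = (nr + tile - 1) / tile;
    cand.resize(ntx * nty);
    for (int tx = 0; tx < ntx; ++tx) {
      int cx = std::min(nc - 1, tx * tile + tile / 2);
      for (int ty = 0; ty < nty; ++ty) {
        int cy = std::min(nr - 1, ty * tile + tile / 2);
        std::vector<int>& v = cand[ty + tx * nty];
        for (int j = 0; j < n; ++j)
          if (Dx(cx, j) + Dy(cy, j) <= rad2) v.push_back(j);
        if (v.empty())
          for (int j = 0; j < n; ++j) v.push_back(j);
      }
    }
  }
  const std::vector<int>& at(int r, int c) const {
    return cand[(r / tile) + (c / tile) * nty];
  }
};

static void assign_labels(const NumericMatrix& Dx, const NumericMatrix& Dy,
                          const std::vector<double>& w, IntegerMatrix& lab,
                          std::vector<int>& counts,
                          const TileCandidates& tc) {
  const int nr = Dy.nrow(), nc = Dx.nrow();
  std::fill(counts.begin(), counts.end(), 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const std::vector<int>& cand = tc.at(r, c);
      double best = R_PosInf;
      int arg = cand[0];
      for (size_t k = 0; k < cand.size(); ++k) {
        int j = cand[k];
        double v = Dx(c, j) + Dy(r, j) - w[j];
        if (v < best) { best = v; arg = j; }
      }
      lab(r, c) = arg + 1;
      counts[arg]++;
    }
  }
}

// Fit per-seed weights by damped fixed-point iteration so realised pixel
// counts approach target_px. Returns labels, weights, iterations and the
// final mean absolute area residual (in pixels, relative to mean target).
// [[Rcpp::export]]
List pd_fit(const NumericMatrix& Dx, const NumericMatrix& Dy,
            NumericVector w0, NumericVector target_px,
            double pixel_area, double eta, double tol, int maxit) {
  const int nr = Dy.nrow(), nc = Dx.nrow(), n = Dx.ncol();
  if (w0.size() != n || target_px.size() != n)
    stop("w0 and target_px must have one entry per seed");
  IntegerMatrix lab(nr, nc);
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<int> counts(n);
  double mean_target = 0.0;
  for (int j = 0; j < n; ++j) mean_target += target_px[j];
  mean_target /= n;
  // candidate radius: 5 mean cell diameters plus the tile extent, um^2
  double rad_um = (5.0 * std::sqrt(mean_target * pixel_area) +
                   24.0 * std::sqrt(pixel_area));
  TileCandidates tc(Dx, Dy, rad_um * rad_um);
  double resid = R_PosInf, best_resid = R_PosInf;
  std::vector<double> best_w(w);
  // per-cell adaptive gain (resilient-propagation style): a cell whose
  // area error flips sign is oscillating around its boundary and gets a
  // smaller step; a cell moving consistently recovers its full step.
  // A single global damping factor cannot serve both the few oscillating
  // cells and the many still-converging ones.
  std::vector<double> gain(n, 1.0), prev_err(n, 0.0);
  int it = 0;
  for (; it < maxit; ++it) {
    assign_labels(Dx, Dy, w, lab, counts, tc);
    resid = 0.0;
    for (int j = 0; j < n; ++j) resid += std::abs(target_px[j] - counts[j]);
    resid /= (n * mean_target);
    if (resid < best_resid) { best_resid = resid; best_w = w; }
    if (resid < tol) break;
    // dA/dw ~ pi/2 for a roughly isotropic cell, so invert with 2/pi
    for (int j = 0; j < n; ++j) {
      double err = target_px[j] - counts[j];
      if (it > 0) {
        if (err * prev_err[j] < 0) gain[j] = std::max(gain[j] * 0.5, 0.02);
        else gain[j] = std::min(gain[j] * 1.1, 1.0);
      }
      prev_err[j] = err;
      double delta = eta * gain[j] * err * pixel_area * 2.0 / M_PI;
      // a vanished cell gets a strong push back into the diagram
      if (counts[j] == 0)
        delta = std::max(delta,
                         eta * gain[j] * mean_target * pixel_area * 2.0 / M_PI);
      w[j] += delta;
    }
  }
  if (resid >= tol && best_resid < resid) {
    // re-evaluate the best-seen weights so labels match the returned state
    w = best_w;
    assign_labels(Dx, Dy, w, lab, counts, tc);
    resid = best_resid;
  }
  return List::create(_["labels"] = lab,
                      _["weights"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = it,
                      _["resid"] = resid);
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) parent[a] = b; }
};

// Number of 4-connected components per label value (index = label).
// [[Rcpp::export]]
IntegerVector label_component_counts(const IntegerMatrix& lab, bool periodic) {
  const int nr = lab.nrow(), nc = lab.ncol();
  UnionFind uf(nr * nc);
  int maxlab = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > maxlab) maxlab = l;
      int i = r + c * nr;
      if (r + 1 < nr && lab(r + 1, c) == l) uf.unite(i, i + 1);
      else if (periodic && r + 1 == nr && lab(0, c) == l) uf.unite(i, c * nr);
      if (c + 1 < nc && lab(r, c + 1) == l) uf.unite(i, i + nr);
      else if (periodic && c + 1 == nc && lab(r, 0) == l) uf.unite(i, r);
    }
  std::vector<std::map<int, bool> > roots(maxlab + 1);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l >= 0) roots[l][uf.find(r + c * nr)] = true;
    }
  IntegerVector out(maxlab + 1);
  for (int l = 0; l <= maxlab; ++l) out[l] = (int)roots[l].size();
  return out;  // out[0] refers to label 0 (background), out[l] to label l
}

// Map of 4-connected components (components never cross label borders):
// integer matrix of component ids 1..K, in scan order of first pixel.
// [[Rcpp::export]]
IntegerMatrix component_map(const IntegerMatrix& lab, bool periodic) {
  const int nr = lab.nrow(), nc = lab.ncol();
  UnionFind uf(nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      int i = r + c * nr;
      if (r + 1 < nr && lab(r + 1, c) == l) uf.unite(i, i + 1);
      else if (periodic && r + 1 == nr && lab(0, c) == l) uf.unite(i, c * nr);
      if (c + 1 < nc && lab(r, c + 1) == l) uf.unite(i, i + nr);
      else if (periodic && c + 1 == nc && lab(r, 0) == l) uf.unite(i, r);
    }
  std::map<int, int> ids;
  IntegerMatrix out(nr, nc);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int root = uf.find(r + c * nr);
      auto it = ids.find(root);
      if (it == ids.end()) { ids[root] = ++next; out(r, c) = next; }
      else out(r, c) = it->second;
    }
  return out;
}

// 6-connected component count per label in a 3D grid (dims attribute set).
// [[Rcpp::export]]
IntegerVector label_component_counts3d(const IntegerVector& lab) {
  IntegerVector dims = lab.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  UnionFind uf((int)ntot);
  int maxlab = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * (y + ny * z);
        int l = lab[i];
        if (l > maxlab) maxlab = l;
        if (x + 1 < nx && lab[i + 1] == l) uf.unite(i, i + 1);
        if (y + 1 < ny && lab[i + nx] == l) uf.unite(i, i + nx);
        if (z + 1 < nz && lab[i + nx * ny] == l) uf.unite(i, i + nx * ny);
      }
  std::vector<std::map<int, bool> > roots(maxlab + 1);
  for (R_xlen_t i = 0; i < ntot; ++i) {
    int l = lab[i];
    if (l >= 0) roots[l][uf.find((int)i)] = true;
  }
  IntegerVector out(maxlab + 1);
  for (int l = 0; l <= maxlab; ++l) out[l] = (int)roots[l].size();
  return out;
}

// Map of 6-connected components of a 3D label grid (components never
// cross label borders); returns component ids 1..K in scan order.
// [[Rcpp::export]]
IntegerVector component_map3d(const IntegerVector& lab) {
  IntegerVector dims = lab.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  UnionFind uf((int)ntot);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * (y + ny * z);
        int l = lab[i];
        if (x + 1 < nx && lab[i + 1] == l) uf.unite(i, i + 1);
        if (y + 1 < ny && lab[i + nx] == l) uf.unite(i, i + nx);
        if (z + 1 < nz && lab[i + nx * ny] == l) uf.unite(i, i + nx * ny);
      }
  std::map<int, int> ids;
  IntegerVector out(ntot);
  int next = 0;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    int root = uf.find((int)i);
    auto it = ids.find(root);
    if (it == ids.end()) { ids[root] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  out.attr("dim") = dims;
  return out;
}

// Count 4-connected boundary pixel-pair contacts between distinct labels.
// Returns a data frame (a, b, count) with a < b; label 0 pairs included so
// callers can treat background explicitly.
// [[Rcpp::export]]
DataFrame contact_counts(const IntegerMatrix& lab, bool periodic) {
  const int nr = lab.nrow(), nc = lab.ncol();
  std::map<std::pair<int, int>, int> cnt;
  auto add = [&](int a, int b) {
    if (a == b) return;
    if (a > b) std::swap(a, b);
    cnt[std::make_pair(a, b)]++;
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (r + 1 < nr) add(l, lab(r + 1, c));
      else if (periodic) add(l, lab(0, c));
      if (c + 1 < nc) add(l, lab(r, c + 1));
      else if (periodic) add(l, lab(r, 0));
    }
  int m = (int)cnt.size();
  IntegerVector a(m), b(m), n(m);
  int i = 0;
  for (auto& kv : cnt) {
    a[i] = kv.first.first; b[i] = kv.first.second; n[i] = kv.second; ++i;
  }
  return DataFrame::create(_["a"] = a, _["b"] = b, _["count"] = n);
}
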