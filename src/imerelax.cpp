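#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Perona-Malik anisotropic diffusion with exponential conductance
// g(|grad|) = exp(-(|grad|/kappa)^2); explicit 4-neighbour update,
// Neumann (replicate) boundaries. lambda must be <= 0.25 for stability.
// [[Rcpp::export(name = ".pm_diffuse")]]
NumericMatrix pm_diffuse(NumericMatrix img, double kappa, double lambda,
                         int niter) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix cur(clone(img)), nxt(nr, nc);
  for (int it = 0; it < niter; ++it) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double c = cur(i, j);
        double dn = (i > 0      ? cur(i - 1, j) : c) - c;
        double ds = (i < nr - 1 ? cur(i + 1, j) : c) - c;
        double dw = (j > 0      ? cur(i, j - 1) : c) - c;
        double de = (j < nc - 1 ? cur(i, j + 1) : c) - c;
        double gn = std::exp(-(dn / kappa) * (dn / kappa));
        double gs = std::exp(-(ds / kappa) * (ds / kappa));
        double gw = std::exp(-(dw / kappa) * (dw / kappa));
        double ge = std::exp(-(de / kappa) * (de / kappa));
        nxt(i, j) = c + lambda * (gn * dn + gs * ds + gw * dw + ge * de);
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Multi-class seeded region growing. A pixel joins the 4-adjacent region
// whose running mean intensity is within tol of the pixel value; after the
// queues exhaust, remaining unassigned pixels are attached (iteratively, in
// deterministic row-major sweeps) to the adjacent class with nearest mean.
// seed_* are 0-based; cls values are 1..nclass. Returns class per pixel.
// [[Rcpp::export(name = ".region_grow")]]
IntegerMatrix region_grow(NumericMatrix img, IntegerVector seed_row,
                          IntegerVector seed_col, IntegerVector seed_cls,
                          int nclass, double tol) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc); // 0 = unassigned
  std::vector<double> sum(nclass + 1, 0.0);
  std::vector<long>   cnt(nclass + 1, 0);
  // FIFO queue of pixels to examine; deterministic: seeds in given order,
  // then breadth-first in neighbour order N,S,W,E.
  std::queue<std::pair<int,int> > q;
  for (int s = 0; s < seed_row.size(); ++s) {
    int i = seed_row[s], j = seed_col[s], c = seed_cls[s];
    if (i < 0 || i >= nr || j < 0 || j >= nc)
      stop("seed outside image");
    if (lab(i, j) != 0 && lab(i, j) != c)
      stop("two seeds of different classes coincide");
    if (lab(i, j) == 0) {
      lab(i, j) = c;
      sum[c] += img(i, j); cnt[c] += 1;
      q.push(std::make_pair(i, j));
    }
  }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int,int> p = q.front(); q.pop();
    int i = p.first, j = p.second, c = lab(i, j);
    for (int d = 0; d < 4; ++d) {
      int ii = i + di[d], jj = j + dj[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (lab(ii, jj) != 0) continue;
      double mean = sum[c] / cnt[c];
      if (std::fabs(img(ii, jj) - mean) <= tol) {
        lab(ii, jj) = c;
        sum[c] += img(ii, jj); cnt[c] += 1;
        q.push(std::make_pair(ii, jj));
      }
    }
  }
  // attach leftovers to neighbouring class with nearest final mean
  std::vector<double> mean(nclass + 1, 0.0);
  for (int c = 1; c <= nclass; ++c)
    mean[c] = cnt[c] ? sum[c] / cnt[c] : R_PosInf;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
      if (lab(i, j) != 0) continue;
      int best = 0; double bestd = R_PosInf;
      for (int d = 0; d < 4; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int c = lab(ii, jj);
        if (c == 0) continue;
        double dd = std::fabs(img(i, j) - mean[c]);
        if (dd < bestd) { bestd = dd; best = c; }
      }
      if (best) { lab(i, j) = best; changed = true; }
    }
  }
  return lab;
}

// 8-connected component labelling of a binary mask (two-pass union-find).
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  // find with path compression
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& pp) : p(pp) {}
    int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[std::max(a,b)] = std::min(a,b); }
  } uf(parent);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int neigh[4]; int nn = 0;
      // previously visited 8-neighbours in column-major scan:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      if (i > 0 && mask(i - 1, j)) neigh[nn++] = lab(i - 1, j);
      if (j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
        if (mask(i, j - 1)) neigh[nn++] = lab(i, j - 1);
        if (i < nr - 1 && mask(i + 1, j - 1)) neigh[nn++] = lab(i + 1, j - 1);
      }
      if (nn == 0) {
        ++next; parent.push_back(next); lab(i, j) = next;
      } else {
        int m = neigh[0];
        for (int t = 1; t < nn; ++t) m = std::min(m, neigh[t]);
        lab(i, j) = m;
        for (int t = 0; t < nn; ++t) uf.unite(m, neigh[t]);
      }
    }
  }
  // relabel compactly
  std::vector<int> remap(next + 1, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!mask(i, j)) continue;
    int r = uf.find(lab(i, j));
    if (!remap[r]) remap[r] = ++k;
    lab(i, j) = remap[r];
  }
  return lab;
}

// Random sequential adsorption of non-overlapping disks in a w x h box.
// Radii ~ lognormal(meanlog, sdlog); centres uniform; a candidate is
// accepted if its centre distance to every placed disk exceeds
// margin * (r_i + r_j). Stops at target area packing or attempt cap.
// Uses R's RNG (seed controlled from R). Returns (x, y, r) rows.
// [[Rcpp::export(name = ".rsa_disks")]]
NumericMatrix rsa_disks(double w, double h, double meanlog, double sdlog,
                        double target_packing, int max_attempts,
                        double margin) {
  std::vector<double> xs, ys, rs;
  double area = w * h, covered = 0.0, rmax = 0.0;
  // coarse cell grid for neighbour queries
  int ncell = 64;
  double cw = w / ncell, ch = h / ncell;
  std::vector< std::vector<int> > cells(ncell * ncell);
  int attempts = 0;
  while (covered / area < target_packing && attempts < max_attempts) {
    ++attempts;
    double r = R::rlnorm(meanlog, sdlog);
    double x = R::runif(0.0, w), y = R::runif(0.0, h);
    double reach = margin * (r + rmax);
    int j0 = std::max(0, (int)((x - reach) / cw)), j1 = std::min(ncell - 1, (int)((x + reach) / cw));
    int i0 = std::max(0, (int)((y - reach) / ch)), i1 = std::min(ncell - 1, (int)((y + reach) / ch));
    bool ok = true;
    for (int ci = i0; ok && ci <= i1; ++ci) {
      for (int cj = j0; ok && cj <= j1; ++cj) {
        const std::vector<int>& cell = cells[ci * ncell + cj];
        for (size_t t = 0; t < cell.size(); ++t) {
          int u = cell[t];
          double dx = x - xs[u], dy = y - ys[u];
          double lim = margin * (r + rs[u]);
          if (dx * dx + dy * dy < lim * lim) { ok = false; break; }
        }
      }
    }
    if (!ok) continue;
    int id = xs.size();
    xs.push_back(x); ys.push_back(y); rs.push_back(r);
    rmax = std::max(rmax, r);
    int cj = std::min(ncell - 1, (int)(x / cw));
    int ci = std::min(ncell - 1, (int)(y / ch));
    cells[ci * ncell + cj].push_back(id);
    covered += M_PI * r * r;
  }
  NumericMatrix out(xs.size(), 3);
  for (size_t t = 0; t < xs.size(); ++t) {
    out(t, 0) = xs[t]; out(t, 1) = ys[t]; out(t, 2) = rs[t];
  }
  return out;
}
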