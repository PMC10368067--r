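#include <Rcpp.h>
using namespace Rcpp;

// Union-find over voxel linear indices (flattened H x W x S array,
// column-major as stored by R). Connectivity 6 = face neighbours,
// 26 = face + edge + corner neighbours. A single-slice volume under
// 26-connectivity is exactly 8-connectivity 2-D labeling.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int H = dims[0], W = dims[1], S = dims[2];
  const R_xlen_t n = (R_xlen_t)H * W * S;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> fg_id(n, -1);   // dense voxel -> foreground index
  std::vector<int> fg_lin;         // foreground index -> linear voxel
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == TRUE) { fg_id[i] = (int)fg_lin.size(); fg_lin.push_back((int)i); }
  }
  const int m = (int)fg_lin.size();
  std::vector<int> parent(m);
  for (int i = 0; i < m; ++i) parent[i] = i;

  // offsets to previously-visited neighbours (raster order)
  for (int k = 0; k < m; ++k) {
    int lin = fg_lin[k];
    int s = lin / (H * W), rem = lin % (H * W);
    int c = rem / H, r = rem % H;
    for (int ds = -1; ds <= 0; ++ds) {
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          if (ds == 0 && dc > 0) continue;
          if (ds == 0 && dc == 0 && dr >= 0) continue;  // raster-previous only
          int nman = std::abs(dr) + std::abs(dc) + std::abs(ds);
          if (connectivity == 6 && nman != 1) continue;
          int rr = r + dr, cc = c + dc, ss = s + ds;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W || ss < 0) continue;
          int nlin = ss * H * W + cc * H + rr;
          if (fg_id[nlin] >= 0) uf_union(parent, k, fg_id[nlin]);
        }
      }
    }
  }

  // compact labels in raster order of component representative first voxel
  std::vector<int> label_of_root(m, 0);
  int next = 0;
  IntegerVector out(n, 0);
  for (int k = 0; k < m; ++k) {
    int root = uf_find(parent, k);
    if (label_of_root[root] == 0) label_of_root[root] = ++next;
    out[fg_lin[k]] = label_of_root[root];
  }
  out.attr("n_labels") = next;
  return out;
}

// Squared Euclidean distance transform, Felzenszwalb & Huttenlocher
// lower-envelope algorithm, separable over the three axes with
// anisotropic spacing. Input: mask (TRUE = feature set); output:
// squared distance to the nearest TRUE voxel.

static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z,
                   int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;  // parabola at infinite height never wins
    double s = 0.0;
    while (k >= 0) {
      if (f[v[k]] == INF) {
        s = -INF;  // infinite parabola is dominated everywhere
      } else {
        s = ((f[q] + s2 * (double)q * q) - (f[v[k]] + s2 * (double)v[k] * v[k])) /
            (2.0 * s2 * (q - v[k]));
      }
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    if (f[v[k]] == INF) {
      d[q] = INF;
    } else {
      double dq = (double)(q - v[k]) * step;
      d[q] = dq * dq + f[v[k]];
    }
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int H = dims[0], W = dims[1], S = dims[2];
  const R_xlen_t n = (R_xlen_t)H * W * S;
  if (mask.size() != n) stop("mask length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  // spacing given as (dz, dy, dx) for array dims (H=y, W=x, S=z)
  const double dy = spacing[1], dx = spacing[2], dz = spacing[0];

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int maxdim = std::max(H, std::max(W, S));
  std::vector<double> f(maxdim), d(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);

  // pass along rows (y, length H)
  for (int s = 0; s < S; ++s)
    for (int c = 0; c < W; ++c) {
      R_xlen_t base = (R_xlen_t)s * H * W + (R_xlen_t)c * H;
      for (int r = 0; r < H; ++r) f[r] = out[base + r];
      edt_1d(f, d, v, z, H, dy);
      for (int r = 0; r < H; ++r) out[base + r] = d[r];
    }
  // pass along columns (x, length W)
  for (int s = 0; s < S; ++s)
    for (int r = 0; r < H; ++r) {
      R_xlen_t base = (R_xlen_t)s * H * W + r;
      for (int c = 0; c < W; ++c) f[c] = out[base + (R_xlen_t)c * H];
      edt_1d(f, d, v, z, W, dx);
      for (int c = 0; c < W; ++c) out[base + (R_xlen_t)c * H] = d[c];
    }
  // pass along slices (z, length S)
  if (S > 1) {
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        R_xlen_t base = (R_xlen_t)c * H + r;
        for (int s = 0; s < S; ++s) f[s] = out[base + (R_xlen_t)s * H * W];
        edt_1d(f, d, v, z, S, dz);
        for (int s = 0; s < S; ++s) out[base + (R_xlen_t)s * H * W] = d[s];
      }
  }
  return out;
}
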