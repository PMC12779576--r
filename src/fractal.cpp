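#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

typedef std::vector<unsigned char> Buf;

// Binary dilation along the first axis of an (a, b, c) column-major buffer
// with a centred-free segment of `w` voxels: output extent a + w - 1.
// Realized as a moving window count; exact Minkowski sum with a segment.
static void dilate_axis0(const Buf &in, int a, int b, int c, int w, Buf &out) {
  const int ao = a + w - 1;
  out.assign((size_t)ao * b * c, 0);
  for (int k = 0; k < c; ++k) {
    for (int j = 0; j < b; ++j) {
      const unsigned char *col = &in[(size_t)a * (j + (size_t)b * k)];
      unsigned char *ocol = &out[(size_t)ao * (j + (size_t)b * k)];
      int run = 0;
      for (int i = 0; i < ao; ++i) {
        if (i < a && col[i]) ++run;
        if (i - w >= 0 && col[i - w]) --run;
        ocol[i] = run > 0 ? 1 : 0;
      }
    }
  }
}

// Rotate axes (a, b, c) -> output dims (b, c, a), out[j, k, i] = in[i, j, k].
static void rotate_axes(const Buf &in, int a, int b, int c, Buf &out) {
  out.resize(in.size());
  for (int k = 0; k < c; ++k)
    for (int j = 0; j < b; ++j) {
      const unsigned char *col = &in[(size_t)a * (j + (size_t)b * k)];
      for (int i = 0; i < a; ++i)
        out[(size_t)j + (size_t)b * (k + (size_t)c * i)] = col[i];
    }
}

// |S (+) B_eps|: cardinality of the dilation of the mask by an eps^3 cube,
// computed separably (cube = Minkowski sum of three orthogonal segments).
static double dilation_cardinality(const Buf &mask, int d1, int d2, int d3,
                                   int eps) {
  if (eps == 1) {
    double s = 0;
    for (size_t i = 0; i < mask.size(); ++i) s += mask[i];
    return s;
  }
  Buf a = mask, b;
  int da = d1, db = d2, dc = d3;
  for (int ax = 0; ax < 3; ++ax) {
    dilate_axis0(a, da, db, dc, eps, b);
    int na = da + eps - 1;
    rotate_axes(b, na, db, dc, a);
    int t = db; db = dc; dc = na; da = t;
  }
  double s = 0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i];
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_dilation_counts(LogicalVector mask, IntegerVector dims,
                                  IntegerVector widths) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  Buf m((size_t)d1 * d2 * d3);
  for (size_t i = 0; i < m.size(); ++i) m[i] = mask[i] == TRUE ? 1 : 0;
  NumericVector out(widths.size());
  for (int s = 0; s < widths.size(); ++s)
    out[s] = dilation_cardinality(m, d1, d2, d3, widths[s]);
  return out;
}

static inline bool surf_at(const Buf &m, int d1, int d2, int d3, int i, int j,
                           int k) {
  size_t idx = (size_t)i + (size_t)d1 * (j + (size_t)d2 * k);
  if (!m[idx]) return false;
  if (i == 0 || i == d1 - 1 || j == 0 || j == d2 - 1 || k == 0 || k == d3 - 1)
    return true;
  size_t s12 = (size_t)d1 * d2;
  return !m[idx - 1] || !m[idx + 1] || !m[idx - d1] || !m[idx + d1] ||
         !m[idx - s12] || !m[idx + s12];
}

// Surface voxels under 6-connectivity; outside the lattice counts as
// background.
// [[Rcpp::export]]
LogicalVector cpp_surface(LogicalVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  Buf m((size_t)d1 * d2 * d3);
  for (size_t i = 0; i < m.size(); ++i) m[i] = mask[i] == TRUE ? 1 : 0;
  LogicalVector out(mask.size());
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i)
        out[(size_t)i + (size_t)d1 * (j + (size_t)d2 * k)] =
            surf_at(m, d1, d2, d3, i, j, k);
  return out;
}

// Recompute surface flags in the box [lo, hi] (inclusive, 0-based) and keep
// the global surface count in step. Returns the new count.
static long update_surface_box(const Buf &m, Buf &surf, int d1, int d2, int d3,
                               int lo1, int hi1, int lo2, int hi2, int lo3,
                               int hi3, long scount) {
  for (int k = lo3; k <= hi3; ++k)
    for (int j = lo2; j <= hi2; ++j)
      for (int i = lo1; i <= hi1; ++i) {
        size_t idx = (size_t)i + (size_t)d1 * (j + (size_t)d2 * k);
        unsigned char ns = surf_at(m, d1, d2, d3, i, j, k) ? 1 : 0;
        if (ns != surf[idx]) {
          scount += ns ? 1 : -1;
          surf[idx] = ns;
        }
      }
  return scount;
}

// Plane <-> cube growth simulation. A seed plane (full x-y extent, one voxel
// thick at z = plane_z, 0-based) either grows by random additions of
// block^3 cubes centred at uniformly drawn surface voxels, or the full
// lattice shrinks by the same rule with the seed plane protected. FD inputs
// (dilation cardinalities at the requested kernel widths), surface and
// foreground counts are recorded at iteration 0, every `stride` iterations,
// and at the final state.
// [[Rcpp::export]]
List cpp_run_sim(IntegerVector dims, int plane_z, int block, int n_iter,
                 int stride, bool grow, IntegerVector widths) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  size_t n = (size_t)d1 * d2 * d3;
  size_t s12 = (size_t)d1 * d2;
  Buf m(n, grow ? 0 : 1), surf(n, 0);
  long fg = 0, scount = 0;
  if (grow) {
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i)
        m[(size_t)i + (size_t)d1 * (j + (size_t)d2 * plane_z)] = 1;
    fg = (long)d1 * d2;
  } else {
    fg = (long)n;
  }
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        size_t idx = (size_t)i + (size_t)d1 * (j + (size_t)d2 * k);
        surf[idx] = surf_at(m, d1, d2, d3, i, j, k) ? 1 : 0;
        if (surf[idx]) ++scount;
      }

  long fg_target = grow ? (long)n : (long)d1 * d2;
  int h = block / 2;
  int nw = widths.size();
  std::vector<double> rec;  // rows of (iter, fg, surf, counts...)
  int ncol = 3 + nw;
  bool terminal = false;

  auto record = [&](int it) {
    rec.push_back(it);
    rec.push_back((double)fg);
    rec.push_back((double)scount);
    for (int s = 0; s < nw; ++s)
      rec.push_back(dilation_cardinality(m, d1, d2, d3, widths[s]));
  };
  record(0);

  int it = 0;
  while (it < n_iter && fg != fg_target) {
    ++it;
    // draw a surface voxel uniformly (rejection against the flag array)
    size_t idx;
    do {
      idx = (size_t)(unif_rand() * n);
      if (idx >= n) idx = n - 1;
    } while (!surf[idx]);
    int ci = (int)(idx % d1);
    int cj = (int)((idx / d1) % d2);
    int ck = (int)(idx / s12);
    int lo1 = std::max(ci - h, 0), hi1 = std::min(ci + h, d1 - 1);
    int lo2 = std::max(cj - h, 0), hi2 = std::min(cj + h, d2 - 1);
    int lo3 = std::max(ck - h, 0), hi3 = std::min(ck + h, d3 - 1);
    for (int k = lo3; k <= hi3; ++k)
      for (int j = lo2; j <= hi2; ++j)
        for (int i = lo1; i <= hi1; ++i) {
          if (!grow && k == plane_z) continue;  // protected seed plane
          size_t q = (size_t)i + (size_t)d1 * (j + (size_t)d2 * k);
          if (grow && !m[q]) {
            m[q] = 1;
            ++fg;
          } else if (!grow && m[q]) {
            m[q] = 0;
            --fg;
          }
        }
    scount = update_surface_box(m, surf, d1, d2, d3, std::max(lo1 - 1, 0),
                                std::min(hi1 + 1, d1 - 1), std::max(lo2 - 1, 0),
                                std::min(hi2 + 1, d2 - 1), std::max(lo3 - 1, 0),
                                std::min(hi3 + 1, d3 - 1), scount);
    if (fg == fg_target) {
      terminal = true;
      record(it);
      break;
    }
    if (it % stride == 0) record(it);
  }
  if (!terminal && (it % stride != 0 || it == 0)) record(it);

  int nrow = (int)(rec.size() / ncol);
  NumericMatrix traj(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int cidx = 0; cidx < ncol; ++cidx)
      traj(r, cidx) = rec[(size_t)r * ncol + cidx];
  return List::create(_["trajectory"] = traj, _["terminal"] = terminal,
                      _["iterations"] = it);
}
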