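// Low-level raster geometry: exact Euclidean distance transform (with the
// nearest-feature map), connected-component labelling, Zhang-Suen thinning,
// sliding-histogram disk median, separable Gaussian blur, and capsule/disk
// rasterizers.  All rasters are row-major R matrices [y, x]; pixel (i, j)
// (0-based here) has its center at ((j + 0.5) * res, (i + 0.5) * res) um.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double DT_INF = 1e30;

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher),
// tracking the argmin site so a feature transform falls out of the 2D pass.
static void dt1d(const std::vector<double>& f, int n,
                 std::vector<double>& d, std::vector<int>& arg) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int vk = v[k];
      s = ((f[q] + (double)q * q) - (f[vk] + (double)vk * vk)) /
          (2.0 * q - 2.0 * vk);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int vk = v[k];
    d[q] = (double)(q - vk) * (q - vk) + f[vk];
    arg[q] = vk;
  }
}

// Exact Euclidean distance (pixel units) from every pixel to the nearest TRUE
// pixel of `mask`, plus the (1-based) row/col of that nearest pixel.
// Pixels are Inf / feature 0 when the mask is empty.
// [[Rcpp::export]]
List cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix dist(nr, nc);
  IntegerMatrix frow(nr, nc), fcol(nr, nc);

  // pass 1: per-column 1D EDT on the binary indicator, remembering the row
  std::vector<double> g(nr * (size_t)nc);
  std::vector<int> grow(nr * (size_t)nc);
  {
    std::vector<double> f(nr), d(nr);
    std::vector<int> arg(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : DT_INF;
      dt1d(f, nr, d, arg);
      for (int i = 0; i < nr; ++i) {
        g[(size_t)j * nr + i] = d[i];
        // arg row only meaningful when d finite
        grow[(size_t)j * nr + i] = arg[i];
      }
    }
  }
  // pass 2: per-row over the column results
  {
    std::vector<double> f(nc), d(nc);
    std::vector<int> arg(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = g[(size_t)j * nr + i];
      dt1d(f, nc, d, arg);
      for (int j = 0; j < nc; ++j) {
        if (d[j] >= DT_INF) {
          dist(i, j) = R_PosInf;
          frow(i, j) = 0;
          fcol(i, j) = 0;
        } else {
          dist(i, j) = std::sqrt(d[j]);
          int jsrc = arg[j];
          frow(i, j) = grow[(size_t)jsrc * nr + i] + 1;
          fcol(i, j) = jsrc + 1;
        }
      }
    }
  }
  return List::create(_["dist"] = dist, _["frow"] = frow, _["fcol"] = fcol);
}

// Connected components (4- or 8-connectivity), labels 1..N in raster-scan
// discovery order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dy8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dx4[4] = {-1, 1, 0, 0};
  const int dy4[4] = {0, 0, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  const int* dx = (connectivity == 4) ? dx4 : dx8;
  const int* dy = (connectivity == 4) ? dy4 : dy8;

  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      lab(i0, j0) = next;
      stack.clear();
      stack.push_back(i0 + j0 * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int i = idx % nr, j = idx / nr;
        for (int q = 0; q < nnb; ++q) {
          int ii = i + dy[q], jj = j + dx[q];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Guo-Hall thinning to a 1-px-wide 8-connected skeleton (two
// sub-iterations; avoids the 2-px diagonal staircases Zhang-Suen leaves).
// Pixels outside the image count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> img((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[(size_t)j * nr + i] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[(size_t)j * nr + i];
  };

  std::vector<size_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[(size_t)j * nr + i]) continue;
          // neighbours P2..P9 clockwise starting north
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1),
              p4 = at(i, j + 1),     p5 = at(i + 1, j + 1),
              p6 = at(i + 1, j),     p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = (sub == 0) ? ((p6 | p7 | (!p9)) & p8)
                             : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            kill.push_back((size_t)j * nr + i);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) img[kill[k]] = 0;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[(size_t)j * nr + i] != 0;
  return out;
}

// Disk median filter via Huang's sliding-histogram algorithm on 16-bit
// integers.  Borders are handled by clamping coordinates (edge replication).
// [[Rcpp::export]]
IntegerMatrix cpp_median_disk(IntegerMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  if (radius < 1) {
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  const int NB = 65536;
  // half-height of the disk at each column offset
  std::vector<int> half(2 * radius + 1);
  long wsize = 0;
  for (int dx = -radius; dx <= radius; ++dx) {
    int h = (int)std::floor(std::sqrt((double)radius * radius - (double)dx * dx));
    half[dx + radius] = h;
    wsize += 2 * h + 1;
  }
  int ktarget = (int)((wsize + 1) / 2);  // lower median

  auto clampi = [&](int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  };
  auto val = [&](int i, int j) -> int {
    int v = img(clampi(i, 0, nr - 1), clampi(j, 0, nc - 1));
    if (v < 0) v = 0;
    if (v > 65535) v = 65535;
    return v;
  };

  std::vector<int> hist(NB);
  for (int i = 0; i < nr; ++i) {
    std::fill(hist.begin(), hist.end(), 0);
    // build full window at j = 0
    for (int dx = -radius; dx <= radius; ++dx) {
      int h = half[dx + radius];
      for (int dy = -h; dy <= h; ++dy) hist[val(i + dy, 0 + dx)]++;
    }
    int med = 0;
    long below = 0;  // count of entries < med
    auto settle = [&]() {
      while (below + hist[med] < ktarget) { below += hist[med]; ++med; }
      while (below >= ktarget) { --med; below -= hist[med]; }
    };
    settle();
    out(i, 0) = med;
    for (int j = 1; j < nc; ++j) {
      for (int dy = -radius; dy <= radius; ++dy) {
        int w = half[dy + radius];  // disk is symmetric: x-extent at row dy
        int vout = val(i + dy, j - 1 - w);
        int vin = val(i + dy, j + w);
        hist[vout]--;
        if (vout < med) --below;
        hist[vin]++;
        if (vin < med) ++below;
      }
      settle();
      out(i, j) = med;
    }
  }
  return out;
}

// Separable Gaussian blur with edge replication; kernel truncated at 4 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  if (sigma <= 0) {
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (size_t t = 0; t < k.size(); ++t) k[t] /= s;

  NumericMatrix tmp(nr, nc);
  // vertical
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0;
        if (ii >= nr) ii = nr - 1;
        acc += k[t + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  // horizontal
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0;
        if (jj >= nc) jj = nc - 1;
        acc += k[t + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Rasterize a set of capsules (thick line segments).  `segs` has one row per
// segment with columns x0, y0, x1, y1, radius, all in um.  A pixel is set
// when its center lies within `radius` of the segment.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_tubes(NumericMatrix segs, int nrow, int ncol,
                                  double res) {
  LogicalMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), FALSE);
  int ns = segs.nrow();
  for (int s = 0; s < ns; ++s) {
    double x0 = segs(s, 0), y0 = segs(s, 1);
    double x1 = segs(s, 2), y1 = segs(s, 3);
    double r = segs(s, 4);
    if (r <= 0) continue;
    double xmin = std::min(x0, x1) - r, xmax = std::max(x0, x1) + r;
    double ymin = std::min(y0, y1) - r, ymax = std::max(y0, y1) + r;
    int j0 = std::max(0, (int)std::floor(xmin / res - 0.5));
    int j1 = std::min(ncol - 1, (int)std::ceil(xmax / res - 0.5));
    int i0 = std::max(0, (int)std::floor(ymin / res - 0.5));
    int i1 = std::min(nrow - 1, (int)std::ceil(ymax / res - 0.5));
    double dx = x1 - x0, dy = y1 - y0;
    double L2 = dx * dx + dy * dy;
    double r2 = r * r;
    for (int j = j0; j <= j1; ++j) {
      double px = (j + 0.5) * res;
      for (int i = i0; i <= i1; ++i) {
        double py = (i + 0.5) * res;
        double t = 0.0;
        if (L2 > 0) {
          t = ((px - x0) * dx + (py - y0) * dy) / L2;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
        }
        double ex = px - (x0 + t * dx), ey = py - (y0 + t * dy);
        if (ex * ex + ey * ey <= r2) out(i, j) = TRUE;
      }
    }
  }
  return out;
}

// Rasterize disks; `pts` rows are (x, y, radius) in um.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_disks(NumericMatrix pts, int nrow, int ncol,
                                  double res) {
  LogicalMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), FALSE);
  int np = pts.nrow();
  for (int p = 0; p < np; ++p) {
    double cx = pts(p, 0), cy = pts(p, 1), r = pts(p, 2);
    if (r <= 0) continue;
    int j0 = std::max(0, (int)std::floor((cx - r) / res - 0.5));
    int j1 = std::min(ncol - 1, (int)std::ceil((cx + r) / res - 0.5));
    int i0 = std::max(0, (int)std::floor((cy - r) / res - 0.5));
    int i1 = std::min(nrow - 1, (int)std::ceil((cy + r) / res - 0.5));
    double r2 = r * r;
    for (int j = j0; j <= j1; ++j) {
      double ex = (j + 0.5) * res - cx;
      for (int i = i0; i <= i1; ++i) {
        double ey = (i + 0.5) * res - cy;
        if (ex * ex + ey * ey <= r2) out(i, j) = TRUE;
      }
    }
  }
  return out;
}

// Exact Euclidean distance to the nearest TRUE pixel by direct search
// (bucketed expanding-ring nearest-neighbour), sharing no code with the
// two-pass EDT above; used as its independent test oracle on small images.
// [[Rcpp::export]]
NumericMatrix cpp_bruteforce_dist(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<int> fi, fj;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) { fi.push_back(i); fj.push_back(j); }
  if (fi.empty()) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  const int cell = 16;
  int gr = (nr + cell - 1) / cell, gc = (nc + cell - 1) / cell;
  std::vector<std::vector<int>> bucket((size_t)gr * gc);
  for (size_t k = 0; k < fi.size(); ++k)
    bucket[(size_t)(fj[k] / cell) * gr + fi[k] / cell].push_back((int)k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j)) { out(i, j) = 0.0; continue; }
      int gi = i / cell, gj = j / cell;
      double best = 1e30;
      int maxring = (gr > gc ? gr : gc);
      for (int ring = 0; ring <= maxring; ++ring) {
        // smallest possible distance from (i,j) to a cell on this ring
        if (ring > 0) {
          double mind = (ring - 1) * (double)cell;
          if (mind * mind > best) break;
        }
        for (int cj = gj - ring; cj <= gj + ring; ++cj) {
          if (cj < 0 || cj >= gc) continue;
          for (int ci = gi - ring; ci <= gi + ring; ++ci) {
            if (ci < 0 || ci >= gr) continue;
            if (ring > 0 && ci != gi - ring && ci != gi + ring &&
                cj != gj - ring && cj != gj + ring) continue;
            const std::vector<int>& b = bucket[(size_t)cj * gr + ci];
            for (size_t t = 0; t < b.size(); ++t) {
              double di = fi[b[t]] - i, dj = fj[b[t]] - j;
              double d2 = di * di + dj * dj;
              if (d2 < best) best = d2;
            }
          }
        }
      }
      out(i, j) = std::sqrt(best);
    }
  }
  return out;
}

// 8-neighbour count of TRUE pixels, used by the skeleton-graph builder.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int cnt = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj)) ++cnt;
        }
      }
      out(i, j) = cnt;
    }
  }
  return out;
}
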