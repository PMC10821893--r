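// Pixel-level kernels behind the R-facing image operators.
// Images are R matrices [y, x] (column-major, y fastest); volumes are
// passed as flat vectors with explicit (ny, nx, nz) dims, linear index
// i = y + ny * (x + nx * z).

#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <queue>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---- 3x3 median despeckle, nearest-neighbour edge padding ----

// [[Rcpp::export]]
NumericMatrix cpp_median3x3(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double v[9];
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int k = 0;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = std::min(std::max(x + dx, 0), W - 1);
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = std::min(std::max(y + dy, 0), H - 1);
          v[k++] = img(yy, xx);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(y, x) = v[4];
    }
  }
  return out;
}

// ---- grayscale erosion/dilation with a non-flat ball (spherical cap)
//      structuring element; out-of-bounds neighbours are skipped, which
//      is equivalent to padding with +/- infinity ----

struct BallSE {
  std::vector<int> dy, dx;
  std::vector<double> h;
};

static BallSE make_ball(double radius) {
  BallSE se;
  int R = (int)std::floor(radius);
  for (int dx = -R; dx <= R; ++dx)
    for (int dy = -R; dy <= R; ++dy) {
      double d2 = (double)dx * dx + (double)dy * dy;
      if (d2 <= radius * radius) {
        se.dy.push_back(dy);
        se.dx.push_back(dx);
        se.h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  return se;
}

static NumericMatrix ball_morph(const NumericMatrix& img, double radius,
                                bool erode) {
  const int H = img.nrow(), W = img.ncol();
  BallSE se = make_ball(radius);
  const int R = (int)std::floor(radius);
  const int PH = H + 2 * R, PW = W + 2 * R;
  const double fill = erode ? DBL_MAX : -DBL_MAX;
  std::vector<double> pad((size_t)PH * PW, fill);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      pad[(size_t)(y + R) + (size_t)PH * (x + R)] = img(y, x);

  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), fill);
  double* o = out.begin();
  const size_t n_off = se.h.size();
  for (size_t k = 0; k < n_off; ++k) {
    const int dy = se.dy[k], dx = se.dx[k];
    const double h = erode ? se.h[k] : -se.h[k];
    for (int x = 0; x < W; ++x) {
      const double* p = &pad[(size_t)(R + dy) + (size_t)PH * (x + R + dx)];
      double* oc = o + (size_t)H * x;
      if (erode) {
        for (int y = 0; y < H; ++y) {
          double v = p[y] - h;
          oc[y] = v < oc[y] ? v : oc[y];
        }
      } else {
        for (int y = 0; y < H; ++y) {
          double v = p[y] - h;  // h already negated: p + |h|
          oc[y] = v > oc[y] ? v : oc[y];
        }
      }
    }
  }
  // a fully padded neighbourhood cannot occur (centre offset is always valid)
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_erode(NumericMatrix img, double radius) {
  return ball_morph(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_dilate(NumericMatrix img, double radius) {
  return ball_morph(img, radius, false);
}

// ---- separable 2D Gaussian blur, reflective boundary ----

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  int R = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * R + 1);
  double s = 0.0;
  for (int i = -R; i <= R; ++i) {
    k[i + R] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + R];
  }
  for (double& v : k) v /= s;

  auto reflect = [](int i, int n) {
    // reflect about the edge pixels (ImageJ-style mirror without repeat)
    while (i < 0 || i >= n) {
      if (i < 0) i = -i;
      if (i >= n) i = 2 * n - 2 - i;
    }
    return i;
  };

  NumericMatrix tmp(H, W), out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int i = -R; i <= R; ++i) acc += k[i + R] * img(reflect(y + i, H), x);
      tmp(y, x) = acc;
    }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int i = -R; i <= R; ++i) acc += k[i + R] * tmp(y, reflect(x + i, W));
      out(y, x) = acc;
    }
  return out;
}

// ---- 3D connected-component labelling (6/26-connectivity), BFS,
//      labels assigned in raster-scan first-encounter order ----

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int ny, int nx, int nz,
                          int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  std::vector<int> off_y, off_x, off_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        if (connectivity == 6 &&
            std::abs(dy) + std::abs(dx) + std::abs(dz) != 1)
          continue;
        off_y.push_back(dy);
        off_x.push_back(dx);
        off_z.push_back(dz);
      }
  const size_t N = (size_t)ny * nx * nz;
  IntegerVector lab(N, 0);
  int next = 0;
  std::vector<int> stack;
  for (size_t i = 0; i < N; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int y = cur % ny, x = (cur / ny) % nx, z = cur / (ny * nx);
      for (size_t k = 0; k < off_y.size(); ++k) {
        int yy = y + off_y[k], xx = x + off_x[k], zz = z + off_z[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        int j = yy + ny * (xx + nx * zz);
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// ---- maxima by prominence flooding (2D, 8-connectivity) ----
//
// Candidate maxima are connected equal-value plateaus with no strictly
// higher neighbour inside the region. A candidate of value v is accepted
// iff (a) v > tolerance, (b) the flood over region pixels of value
// > v - tolerance reachable from the plateau contains no strictly higher
// pixel, and (c) no equal-value candidate with a smaller minimum linear
// index lies in that flood (equal maxima within tolerance merge to one
// reported point). Accepted candidates report their plateau centroid.

// [[Rcpp::export]]
NumericMatrix cpp_find_maxima(NumericMatrix img, LogicalMatrix region,
                              double tolerance) {
  const int H = img.nrow(), W = img.ncol();
  const int N = H * W;
  std::vector<int> plat(N, 0);  // plateau id, 0 = not in region
  std::vector<int> stack;

  const int dys[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dxs[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

  // label equal-value plateaus within region
  int np = 0;
  for (int i = 0; i < N; ++i) {
    if (!region[i] || plat[i]) continue;
    ++np;
    plat[i] = np;
    stack.clear();
    stack.push_back(i);
    const double v = img[i];
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int y = cur % H, x = cur / H;
      for (int k = 0; k < 8; ++k) {
        int yy = y + dys[k], xx = x + dxs[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        int j = yy + H * xx;
        if (region[j] && !plat[j] && img[j] == v) {
          plat[j] = np;
          stack.push_back(j);
        }
      }
    }
  }

  // plateau stats: value, min linear index, centroid, local-max flag
  std::vector<double> pval(np + 1, 0.0), psy(np + 1, 0.0), psx(np + 1, 0.0);
  std::vector<int> pmin(np + 1, N), pn(np + 1, 0);
  std::vector<char> ismax(np + 1, 1);
  for (int i = 0; i < N; ++i) {
    int p = plat[i];
    if (!p) continue;
    pval[p] = img[i];
    if (i < pmin[p]) pmin[p] = i;
    int y = i % H, x = i / H;
    psy[p] += y;
    psx[p] += x;
    pn[p] += 1;
    for (int k = 0; k < 8; ++k) {
      int yy = y + dys[k], xx = x + dxs[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      int j = yy + H * xx;
      if (region[j] && img[j] > img[i]) {
        ismax[p] = 0;
        break;
      }
    }
  }

  // pixel lists per plateau (counting sort)
  std::vector<int> pstart(np + 2, 0), ppix(0);
  {
    for (int i = 0; i < N; ++i)
      if (plat[i]) ++pstart[plat[i] + 1];
    for (int p = 1; p <= np + 1; ++p) pstart[p] += pstart[p - 1];
    ppix.resize(pstart[np + 1]);
    std::vector<int> fill_at(pstart.begin(), pstart.end() - 1);
    for (int i = 0; i < N; ++i)
      if (plat[i]) ppix[fill_at[plat[i]]++] = i;
  }

  std::vector<int> cand;
  for (int p = 1; p <= np; ++p)
    if (ismax[p] && pval[p] > tolerance) cand.push_back(p);
  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (pval[a] != pval[b]) return pval[a] > pval[b];
    return pmin[a] < pmin[b];
  });

  std::vector<int> stamp(N, 0);
  std::vector<double> out_y, out_x, out_v;
  int cur_stamp = 0;

  for (int p : cand) {
    const double v = pval[p], lo = v - tolerance;
    ++cur_stamp;
    bool reject = false;
    stack.clear();
    // seed with the plateau
    for (int t = pstart[p]; t < pstart[p + 1]; ++t) {
      stamp[ppix[t]] = cur_stamp;
      stack.push_back(ppix[t]);
    }
    while (!stack.empty() && !reject) {
      int cur = stack.back();
      stack.pop_back();
      int y = cur % H, x = cur / H;
      for (int k = 0; k < 8; ++k) {
        int yy = y + dys[k], xx = x + dxs[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        int j = yy + H * xx;
        if (!region[j] || stamp[j] == cur_stamp) continue;
        if (img[j] > v) {
          reject = true;
          break;
        }
        if (img[j] > lo) {
          int q = plat[j];
          if (q != p && ismax[q] && img[j] == v && pmin[q] < pmin[p]) {
            reject = true;  // merged into an earlier equal maximum
            break;
          }
          stamp[j] = cur_stamp;
          stack.push_back(j);
        }
      }
    }
    if (!reject) {
      out_y.push_back(psy[p] / pn[p]);
      out_x.push_back(psx[p] / pn[p]);
      out_v.push_back(v);
    }
  }

  NumericMatrix res((int)out_y.size(), 3);
  for (int i = 0; i < (int)out_y.size(); ++i) {
    res(i, 0) = out_y[i] + 1;  // 1-based, as R matrix indices
    res(i, 1) = out_x[i] + 1;
    res(i, 2) = out_v[i];
  }
  colnames(res) = CharacterVector::create("y", "x", "value");
  return res;
}
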