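// Keypoint detection and description for 8-bit grayscale images.
//
// Two extractors are provided:
//  * a DoG (difference-of-Gaussians) scale-space detector with a 4x4x8
//    gradient-orientation descriptor (128 reals) — the classic SIFT design;
//  * a FAST-9 corner detector on an image pyramid with Harris ranking,
//    intensity-centroid orientation and a steered binary intensity-comparison
//    (BRIEF) descriptor — the ORB design, with a configurable bit count.
//
// Images arrive as R matrices scaled to [0,1]; x is the 0-based column and
// y the 0-based row. Everything is deterministic: there is no RNG, and the
// BRIEF sampling pattern is a fixed table generated from a constant LCG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Img {
  int w = 0, h = 0;
  std::vector<double> d;
  Img() = default;
  Img(int h_, int w_) : w(w_), h(h_), d((size_t)w_ * h_, 0.0) {}
  inline double at(int y, int x) const { return d[(size_t)y * w + x]; }
  inline double& at(int y, int x) { return d[(size_t)y * w + x]; }
  // reflected border access
  inline double atr(int y, int x) const {
    if (x < 0) x = -x;
    if (x >= w) x = 2 * w - 2 - x;
    if (y < 0) y = -y;
    if (y >= h) y = 2 * h - 2 - y;
    return at(y, x);
  }
  inline double bilinear(double y, double x) const {
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    double fx = x - x0, fy = y - y0;
    double v00 = atr(y0, x0), v01 = atr(y0, x0 + 1);
    double v10 = atr(y0 + 1, x0), v11 = atr(y0 + 1, x0 + 1);
    return v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
           v10 * fy * (1 - fx) + v11 * fy * fx;
  }
};

Img from_matrix(const NumericMatrix& m) {
  Img im(m.nrow(), m.ncol());
  for (int y = 0; y < im.h; ++y)
    for (int x = 0; x < im.w; ++x) im.at(y, x) = m(y, x);
  return im;
}

Img gauss_blur(const Img& src, double sigma) {
  if (sigma <= 0.01) return src;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  Img tmp(src.h, src.w), out(src.h, src.w);
  for (int y = 0; y < src.h; ++y)
    for (int x = 0; x < src.w; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * src.atr(y, x + i);
      tmp.at(y, x) = acc;
    }
  for (int y = 0; y < src.h; ++y)
    for (int x = 0; x < src.w; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp.atr(y + i, x);
      out.at(y, x) = acc;
    }
  return out;
}

Img halve(const Img& src) {
  Img out((src.h + 1) / 2, (src.w + 1) / 2);
  for (int y = 0; y < out.h; ++y)
    for (int x = 0; x < out.w; ++x) out.at(y, x) = src.at(2 * y, 2 * x);
  return out;
}

Img resize(const Img& src, int nh, int nw) {
  Img out(nh, nw);
  double sy = (double)src.h / nh, sx = (double)src.w / nw;
  for (int y = 0; y < nh; ++y)
    for (int x = 0; x < nw; ++x)
      out.at(y, x) = src.bilinear((y + 0.5) * sy - 0.5, (x + 0.5) * sx - 0.5);
  return out;
}

struct Kp {
  double x, y, scale, orientation, response;
  int octave, layer; // SIFT bookkeeping
  int level;         // ORB bookkeeping
};

// ---------------------------------------------------------------- SIFT ----

const int SIFT_NSCALES = 3;
const double SIFT_SIGMA0 = 1.6;

void sift_orientations(const Img& g, double x, double y, double sig_oct,
                       std::vector<double>& out_angles) {
  const int NB = 36;
  double hist[NB] = {0};
  double sw = 1.5 * sig_oct;
  int r = (int)std::round(3.0 * sw);
  int xi = (int)std::round(x), yi = (int)std::round(y);
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      int px = xi + dx, py = yi + dy;
      if (px < 1 || px >= g.w - 1 || py < 1 || py >= g.h - 1) continue;
      double gx = g.at(py, px + 1) - g.at(py, px - 1);
      double gy = g.at(py + 1, px) - g.at(py - 1, px);
      double mag = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx); // [-pi, pi]
      double wgt = std::exp(-(dx * dx + dy * dy) / (2.0 * sw * sw));
      int bin = (int)std::floor((ang + M_PI) / (2 * M_PI) * NB);
      if (bin >= NB) bin = NB - 1;
      if (bin < 0) bin = 0;
      hist[bin] += mag * wgt;
    }
  // circular smoothing, twice
  for (int pass = 0; pass < 2; ++pass) {
    double sm[NB];
    for (int i = 0; i < NB; ++i)
      sm[i] = 0.25 * hist[(i + NB - 1) % NB] + 0.5 * hist[i] +
              0.25 * hist[(i + 1) % NB];
    std::copy(sm, sm + NB, hist);
  }
  double mx = *std::max_element(hist, hist + NB);
  if (mx <= 0) { out_angles.push_back(0.0); return; }
  for (int i = 0; i < NB; ++i) {
    double l = hist[(i + NB - 1) % NB], c = hist[i], rr = hist[(i + 1) % NB];
    if (c >= 0.8 * mx && c > l && c > rr) {
      double off = 0.5 * (l - rr) / (l - 2 * c + rr); // parabolic peak
      double ang = (i + 0.5 + off) / NB * 2 * M_PI - M_PI;
      out_angles.push_back(ang);
    }
  }
  if (out_angles.empty()) out_angles.push_back(0.0);
}

std::vector<double> sift_descriptor(const Img& g, double x, double y,
                                    double sig_oct, double theta) {
  const int D = 4, NB = 8;
  double desc[D * D * NB] = {0};
  double binw = 3.0 * sig_oct;                 // spatial bin width, pixels
  double radius = binw * (D + 1) * 0.5 * M_SQRT2;
  double ct = std::cos(theta), st = std::sin(theta);
  int r = (int)std::round(radius);
  int xi = (int)std::round(x), yi = (int)std::round(y);
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      int px = xi + dx, py = yi + dy;
      if (px < 1 || px >= g.w - 1 || py < 1 || py >= g.h - 1) continue;
      // rotate offsets into the keypoint frame
      double rx = (ct * dx + st * dy) / binw;
      double ry = (-st * dx + ct * dy) / binw;
      double rbin = ry + D / 2.0 - 0.5, cbin = rx + D / 2.0 - 0.5;
      if (rbin <= -1 || rbin >= D || cbin <= -1 || cbin >= D) continue;
      double gx = g.at(py, px + 1) - g.at(py, px - 1);
      double gy = g.at(py + 1, px) - g.at(py - 1, px);
      double mag = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx) - theta;
      while (ang < 0) ang += 2 * M_PI;
      while (ang >= 2 * M_PI) ang -= 2 * M_PI;
      double obin = ang / (2 * M_PI) * NB;
      double wgt = mag * std::exp(-(rx * rx + ry * ry) / (2.0 * (0.5 * D) * (0.5 * D)));
      int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin),
          o0 = (int)std::floor(obin);
      double fr = rbin - r0, fc = cbin - c0, fo = obin - o0;
      for (int ir = 0; ir <= 1; ++ir) {
        int rb = r0 + ir;
        if (rb < 0 || rb >= D) continue;
        double wr = wgt * (ir ? fr : 1 - fr);
        for (int ic = 0; ic <= 1; ++ic) {
          int cb = c0 + ic;
          if (cb < 0 || cb >= D) continue;
          double wc = wr * (ic ? fc : 1 - fc);
          for (int io = 0; io <= 1; ++io) {
            int ob = (o0 + io) % NB;
            desc[(rb * D + cb) * NB + ob] += wc * (io ? fo : 1 - fo);
          }
        }
      }
    }
  // normalize, clip at 0.2, renormalize (illumination robustness)
  double nrm = 0;
  for (double v : desc) nrm += v * v;
  nrm = std::sqrt(nrm);
  if (nrm > 1e-12)
    for (double& v : desc) v = std::min(v / nrm, 0.2);
  nrm = 0;
  for (double v : desc) nrm += v * v;
  nrm = std::sqrt(nrm);
  std::vector<double> out(D * D * NB);
  for (int i = 0; i < D * D * NB; ++i)
    out[i] = nrm > 1e-12 ? desc[i] / nrm : 0.0;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".sift_extract")]]
List sift_extract_cpp(NumericMatrix image, double contrast_thresh,
                      double edge_thresh, int max_keypoints) {
  Img base = from_matrix(image);
  // bring the assumed 0.5-sigma input up to SIGMA0
  base = gauss_blur(base, std::sqrt(std::max(SIFT_SIGMA0 * SIFT_SIGMA0 - 0.25, 0.01)));
  int n_oct = std::max(1, (int)std::floor(std::log2((double)std::min(base.w, base.h))) - 4);
  n_oct = std::min(n_oct, 4);
  double k = std::pow(2.0, 1.0 / SIFT_NSCALES);
  std::vector<Kp> kps;
  std::vector<std::vector<double>> descs;

  // build and keep the Gaussian pyramids, collect capped candidates, and
  // only then compute orientations and descriptors for the survivors
  struct Cand { int o, s, x, y; double resp; };
  std::vector<Cand> cands;
  std::vector<std::vector<Img>> pyramids;

  Img oct_base = base;
  for (int o = 0; o < n_oct; ++o) {
    if (oct_base.w < 16 || oct_base.h < 16) break;
    std::vector<Img> gauss(SIFT_NSCALES + 3);
    gauss[0] = oct_base;
    double sig_prev = SIFT_SIGMA0;
    for (int s = 1; s < SIFT_NSCALES + 3; ++s) {
      double sig_total = SIFT_SIGMA0 * std::pow(k, s);
      double sig_inc = std::sqrt(sig_total * sig_total - sig_prev * sig_prev);
      gauss[s] = gauss_blur(gauss[s - 1], sig_inc);
      sig_prev = sig_total;
    }
    std::vector<Img> dog(SIFT_NSCALES + 2);
    for (int s = 0; s < SIFT_NSCALES + 2; ++s) {
      dog[s] = Img(oct_base.h, oct_base.w);
      for (size_t i = 0; i < dog[s].d.size(); ++i)
        dog[s].d[i] = gauss[s + 1].d[i] - gauss[s].d[i];
    }
    int border = 8;
    for (int s = 1; s <= SIFT_NSCALES; ++s) {
      const Img &d0 = dog[s - 1], &d1 = dog[s], &d2 = dog[s + 1];
      for (int y = border; y < oct_base.h - border; ++y)
        for (int x = border; x < oct_base.w - border; ++x) {
          double v = d1.at(y, x);
          if (std::fabs(v) < contrast_thresh) continue;
          // ties break toward the earlier grid position so a symmetric
          // plateau (peak exactly between two samples) yields one extremum
          bool mx = true, mn = true;
          for (int ds2 = -1; ds2 <= 1 && (mx || mn); ++ds2) {
            const Img& dd = ds2 < 0 ? d0 : (ds2 == 0 ? d1 : d2);
            for (int dy = -1; dy <= 1 && (mx || mn); ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (ds2 == 0 && dy == 0 && dx == 0) continue;
                double nv = dd.at(y + dy, x + dx);
                bool before = ds2 < 0 ||
                  (ds2 == 0 && (dy < 0 || (dy == 0 && dx < 0)));
                if (before ? nv >= v : nv > v) mx = false;
                if (before ? nv <= v : nv < v) mn = false;
                if (!mx && !mn) break;
              }
          }
          if (!mx && !mn) continue;
          // edge rejection on the 2x2 spatial Hessian
          double dxx = d1.at(y, x + 1) + d1.at(y, x - 1) - 2 * v;
          double dyy = d1.at(y + 1, x) + d1.at(y - 1, x) - 2 * v;
          double dxy = 0.25 * (d1.at(y + 1, x + 1) - d1.at(y + 1, x - 1) -
                               d1.at(y - 1, x + 1) + d1.at(y - 1, x - 1));
          double tr = dxx + dyy, det = dxx * dyy - dxy * dxy;
          double r = edge_thresh;
          if (det <= 0 || tr * tr * r >= (r + 1) * (r + 1) * det) continue;
          cands.push_back({o, s, x, y, std::fabs(v)});
        }
    }
    pyramids.push_back(std::move(gauss));
    oct_base = halve(pyramids.back()[SIFT_NSCALES]);
  }

  if (max_keypoints > 0 && (int)cands.size() > max_keypoints) {
    std::vector<int> idx(cands.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return cands[a].resp > cands[b].resp;
    });
    idx.resize(max_keypoints);
    std::sort(idx.begin(), idx.end());
    std::vector<Cand> kept;
    kept.reserve(idx.size());
    for (int i : idx) kept.push_back(cands[i]);
    cands.swap(kept);
  }

  for (const Cand& c : cands) {
    const Img& g = pyramids[c.o][c.s];
    double sig_oct = SIFT_SIGMA0 * std::pow(k, c.s);
    double scale0 = std::pow(2.0, c.o);
    std::vector<double> angles;
    sift_orientations(g, c.x, c.y, sig_oct, angles);
    for (double th : angles) {
      Kp kp;
      kp.x = c.x * scale0; kp.y = c.y * scale0;
      kp.scale = sig_oct * scale0;
      kp.orientation = th;
      kp.response = c.resp;
      kp.octave = c.o; kp.layer = c.s; kp.level = 0;
      kps.push_back(kp);
      descs.push_back(sift_descriptor(g, c.x, c.y, sig_oct, th));
    }
  }

  int n = kps.size();
  NumericVector X(n), Y(n), S(n), O(n), R(n);
  NumericMatrix D(n, 128);
  for (int i = 0; i < n; ++i) {
    X[i] = kps[i].x; Y[i] = kps[i].y; S[i] = kps[i].scale;
    O[i] = kps[i].orientation; R[i] = kps[i].response;
    for (int j = 0; j < 128; ++j) D(i, j) = descs[i][j];
  }
  return List::create(_["x"] = X, _["y"] = Y, _["scale"] = S,
                      _["orientation"] = O, _["response"] = R,
                      _["descriptors"] = D);
}

// ----------------------------------------------------------------- ORB ----

namespace {

const int CIRCLE16[16][2] = { // (dx, dy), Bresenham circle radius 3
  {0, -3}, {1, -3}, {2, -2}, {3, -1}, {3, 0}, {3, 1}, {2, 2}, {1, 3},
  {0, 3}, {-1, 3}, {-2, 2}, {-3, 1}, {-3, 0}, {-3, -1}, {-2, -2}, {-1, -3}
};

// FAST-9 segment test; returns a corner score (sum of threshold excess) or 0.
double fast9_score(const Img& im, int y, int x, double t) {
  double p = im.at(y, x);
  // quick reject on the four compass points: a 9-contiguous arc needs at
  // least three of them on the same side of the threshold
  int hi = 0, lo = 0;
  for (int i : {0, 4, 8, 12}) {
    double d = im.at(y + CIRCLE16[i][1], x + CIRCLE16[i][0]) - p;
    if (d > t) ++hi;
    if (d < -t) ++lo;
  }
  if (hi < 3 && lo < 3) return 0.0;
  double diff[24];
  for (int i = 0; i < 24; ++i) {
    const int* c = CIRCLE16[i % 16];
    diff[i] = im.at(y + c[1], x + c[0]) - p;
  }
  // brighter arc
  double best = 0;
  for (int sign = 0; sign < 2; ++sign) {
    int run = 0;
    double acc = 0, bestArc = 0;
    for (int i = 0; i < 24; ++i) {
      double d = sign ? -diff[i] : diff[i];
      if (d > t) {
        ++run; acc += d - t;
        if (run >= 9 && acc > bestArc) bestArc = acc;
      } else { run = 0; acc = 0; }
    }
    if (bestArc > best) best = bestArc;
  }
  return best;
}

double harris_response(const Img& im, int y, int x) {
  double a = 0, b = 0, c = 0; // Ixx, Iyy, Ixy sums over 7x7
  for (int dy = -3; dy <= 3; ++dy)
    for (int dx = -3; dx <= 3; ++dx) {
      int px = x + dx, py = y + dy;
      if (px < 1 || px >= im.w - 1 || py < 1 || py >= im.h - 1) continue;
      double gx = im.at(py, px + 1) - im.at(py, px - 1);
      double gy = im.at(py + 1, px) - im.at(py - 1, px);
      a += gx * gx; b += gy * gy; c += gx * gy;
    }
  return a * b - c * c - 0.04 * (a + b) * (a + b);
}

double ic_orientation(const Img& im, int y, int x, int radius) {
  double m01 = 0, m10 = 0;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx) {
      if (dx * dx + dy * dy > radius * radius) continue;
      int px = x + dx, py = y + dy;
      if (px < 0 || px >= im.w || py < 0 || py >= im.h) continue;
      double v = im.at(py, px);
      m10 += dx * v; m01 += dy * v;
    }
  return std::atan2(m01, m10);
}

// Fixed BRIEF sampling pattern: `nbits` point pairs drawn uniformly from a
// 27x27 patch by a constant LCG, so the pattern is identical across calls,
// platforms and sessions.
void brief_pattern(int nbits, std::vector<int>& pat) {
  pat.resize(nbits * 4);
  unsigned long long state = 88172645463325252ULL;
  auto nextint = [&]() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return (int)((state >> 33) % 27) - 13; // [-13, 13]
  };
  for (int i = 0; i < nbits * 4; ++i) pat[i] = nextint();
}

} // namespace

// [[Rcpp::export(name = ".orb_extract")]]
List orb_extract_cpp(NumericMatrix image, double fast_thresh, int n_levels,
                     double scale_factor, int max_keypoints, int nbits) {
  Img level0 = from_matrix(image);
  std::vector<int> pattern;
  brief_pattern(nbits, pattern);

  struct Cand { double x0, y0, resp, theta; int level; std::vector<int> bits; };
  std::vector<Cand> cands;

  Img lev = level0;
  double sc = 1.0;
  for (int L = 0; L < n_levels; ++L) {
    if (L > 0) {
      int nh = (int)std::round(level0.h / std::pow(scale_factor, L));
      int nw = (int)std::round(level0.w / std::pow(scale_factor, L));
      if (nh < 40 || nw < 40) break;
      lev = resize(level0, nh, nw);
      sc = std::pow(scale_factor, L);
    }
    Img smooth = gauss_blur(lev, 2.0);
    int border = 17; // room for orientation patch and rotated BRIEF samples
    Img score(lev.h, lev.w);
    for (int y = border; y < lev.h - border; ++y)
      for (int x = border; x < lev.w - border; ++x)
        score.at(y, x) = fast9_score(lev, y, x, fast_thresh);
    for (int y = border; y < lev.h - border; ++y)
      for (int x = border; x < lev.w - border; ++x) {
        double s = score.at(y, x);
        if (s <= 0) continue;
        bool ismax = true;
        for (int dy = -1; dy <= 1 && ismax; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0) continue;
            double sn = score.at(y + dy, x + dx);
            if (sn > s || (sn == s && (dy < 0 || (dy == 0 && dx < 0)))) {
              ismax = false; break;
            }
          }
        if (!ismax) continue;
        Cand cd;
        cd.x0 = x * sc; cd.y0 = y * sc; cd.level = L;
        cd.resp = harris_response(smooth, y, x);
        cd.theta = ic_orientation(smooth, y, x, 15);
        double ct = std::cos(cd.theta), st = std::sin(cd.theta);
        cd.bits.resize(nbits);
        for (int b = 0; b < nbits; ++b) {
          double px = pattern[4 * b], py = pattern[4 * b + 1];
          double qx = pattern[4 * b + 2], qy = pattern[4 * b + 3];
          double rpx = ct * px - st * py, rpy = st * px + ct * py;
          double rqx = ct * qx - st * qy, rqy = st * qx + ct * qy;
          double ip = smooth.bilinear(y + rpy, x + rpx);
          double iq = smooth.bilinear(y + rqy, x + rqx);
          cd.bits[b] = ip < iq ? 1 : 0;
        }
        cands.push_back(std::move(cd));
      }
  }

  // rank by Harris response, stable order for ties
  std::vector<int> idx(cands.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    return cands[a].resp > cands[b].resp;
  });
  if (max_keypoints > 0 && (int)idx.size() > max_keypoints)
    idx.resize(max_keypoints);

  int n = idx.size();
  NumericVector X(n), Y(n), S(n), O(n), R(n);
  IntegerMatrix D(n, nbits);
  for (int i = 0; i < n; ++i) {
    const Cand& c = cands[idx[i]];
    X[i] = c.x0; Y[i] = c.y0;
    S[i] = std::pow(scale_factor, c.level);
    O[i] = c.theta; R[i] = c.resp;
    for (int j = 0; j < nbits; ++j) D(i, j) = c.bits[j];
  }
  return List::create(_["x"] = X, _["y"] = Y, _["scale"] = S,
                      _["orientation"] = O, _["response"] = R,
                      _["descriptors"] = D);
}
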