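#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// World-anchored texture noise: a pixel's noise depends only on which surface
// cell the ray hits (primitive id + quantised surface coordinates) and the
// scene seed, so texture is stable across viewpoints and renders.
static inline uint32_t hash3(uint32_t seed, int32_t id, int32_t u, int32_t v) {
  uint32_t h = seed ^ 0x9e3779b9u;
  h ^= (uint32_t)id * 0x85ebca6bu;
  h = (h << 13) | (h >> 19);
  h = h * 5u + 0xe6546b64u;
  h ^= (uint32_t)u * 0xc2b2ae35u;
  h = (h << 13) | (h >> 19);
  h ^= (uint32_t)v * 0x27d4eb2fu;
  h ^= h >> 16; h *= 0x85ebca6bu;
  h ^= h >> 13; h *= 0xc2b2ae35u;
  h ^= h >> 16;
  return h;
}

static inline double tex_noise(uint32_t seed, int id, double u, double v,
                               double amp) {
  if (amp <= 0.0) return 0.0;
  int32_t ui = (int32_t)std::floor(u);
  int32_t vi = (int32_t)std::floor(v);
  uint32_t h = hash3(seed, id, ui, vi);
  double x = (double)h / 4294967295.0; // [0, 1]
  return std::round((2.0 * x - 1.0) * amp);
}

// Ray-cast one panorama. Bearings are compass-style: degrees clockwise from
// world +y. Column c (0-based) has azimuth ref_bearing + (c + 0.5) * 360 / width;
// row 0 is elevation elev_top degrees, decreasing by one degree per row.
//
// trunks:   n x 5  (x, y, radius, height, intensity) vertical cylinders on z=0
// canopies: n x 5  (x, y, zc, radius, intensity) spheres
// screen:   length 6 (cx, cy, half_width, z0, z1, intensity) or length 0
// [[Rcpp::export]]
NumericMatrix cpp_render_panorama(NumericMatrix trunks, NumericMatrix canopies,
                                  double ground_int, double sky_int,
                                  NumericVector screen,
                                  double vx, double vy, double vz,
                                  double ref_bearing, int width, int height,
                                  double elev_top, double noise_amp,
                                  double noise_amp_bark, int noise_seed) {
  NumericMatrix out(height, width);
  const double d2r = M_PI / 180.0;
  const int nt = trunks.nrow(), nc = canopies.nrow();
  const bool has_screen = screen.size() >= 6;
  const double tmin = 1e-9;
  uint32_t seed = (uint32_t)noise_seed;

  for (int c = 0; c < width; ++c) {
    double az = ref_bearing + (c + 0.5) * (360.0 / width);
    double b = az * d2r;
    double sb = std::sin(b), cb = std::cos(b);
    for (int row = 0; row < height; ++row) {
      double el = (elev_top - row) * d2r;
      double ce = std::cos(el), se = std::sin(el);
      double dx = ce * sb, dy = ce * cb, dz = se;

      double best = R_PosInf, val = sky_int;
      bool hit = false;
      int hid = 0; double hu = 0.0, hv = 0.0;

      // trunks (cylinders, no caps: the inner far wall shows as trunk top)
      double A = dx * dx + dy * dy;
      for (int i = 0; i < nt; ++i) {
        if (A < 1e-14) continue;
        double ox = vx - trunks(i, 0), oy = vy - trunks(i, 1);
        double r = trunks(i, 2), hmax = trunks(i, 3);
        double B = 2.0 * (ox * dx + oy * dy);
        double C = ox * ox + oy * oy - r * r;
        double disc = B * B - 4.0 * A * C;
        if (disc < 0.0) continue;
        double sq = std::sqrt(disc);
        for (int k = 0; k < 2; ++k) {
          double t = (k == 0) ? (-B - sq) / (2.0 * A) : (-B + sq) / (2.0 * A);
          if (t <= tmin || t >= best) continue;
          double z = vz + t * dz;
          if (z < 0.0 || z > hmax) continue;
          best = t; val = trunks(i, 4); hit = true;
          double hx = vx + t * dx - trunks(i, 0);
          double hy = vy + t * dy - trunks(i, 1);
          hid = 100 + i;
          hu = std::atan2(hx, hy) / d2r; // deg cell around the axis
          hv = z * 100.0;                // cm cell in height
          break; // nearer root wins; k loop ordered by t
        }
      }

      // canopies (spheres)
      for (int i = 0; i < nc; ++i) {
        double ox = vx - canopies(i, 0), oy = vy - canopies(i, 1);
        double oz = vz - canopies(i, 2);
        double r = canopies(i, 3);
        double B = 2.0 * (ox * dx + oy * dy + oz * dz);
        double C = ox * ox + oy * oy + oz * oz - r * r;
        double disc = B * B - 4.0 * C; // A = 1 for unit direction
        if (disc < 0.0) continue;
        double sq = std::sqrt(disc);
        for (int k = 0; k < 2; ++k) {
          double t = (k == 0) ? (-B - sq) / 2.0 : (-B + sq) / 2.0;
          if (t <= tmin || t >= best) continue;
          best = t; val = canopies(i, 4); hit = true;
          double hx = vx + t * dx - canopies(i, 0);
          double hy = vy + t * dy - canopies(i, 1);
          double hz = vz + t * dz - canopies(i, 2);
          hid = 200 + i;
          hu = std::atan2(hx, hy) / d2r;
          double hh = std::sqrt(hx * hx + hy * hy);
          hv = std::atan2(hz, hh) / d2r;
          break;
        }
      }

      // screen: four vertical walls of an axis-aligned square
      if (has_screen) {
        double cx = screen[0], cy = screen[1], hw = screen[2];
        double z0 = screen[3], z1 = screen[4], si = screen[5];
        for (int w = 0; w < 4; ++w) {
          double t, along;
          if (w < 2) { // x = cx +/- hw
            if (std::fabs(dx) < 1e-14) continue;
            double px = cx + (w == 0 ? hw : -hw);
            t = (px - vx) / dx;
            if (t <= tmin || t >= best) continue;
            double py = vy + t * dy;
            if (std::fabs(py - cy) > hw) continue;
            along = py;
          } else { // y = cy +/- hw
            if (std::fabs(dy) < 1e-14) continue;
            double py = cy + (w == 2 ? hw : -hw);
            t = (py - vy) / dy;
            if (t <= tmin || t >= best) continue;
            double px = vx + t * dx;
            if (std::fabs(px - cx) > hw) continue;
            along = px;
          }
          double pz = vz + t * dz;
          if (pz < z0 || pz > z1) continue;
          best = t; val = si; hit = true;
          hid = 10 + w; hu = along * 100.0; hv = pz * 100.0;
        }
      }

      // ground plane z = 0
      if (dz < -1e-14) {
        double t = -vz / dz;
        if (t > tmin && t < best) {
          best = t; val = ground_int; hit = true;
          hid = 1;
          hu = (vx + t * dx) * 10.0; // 10 cm cells
          hv = (vy + t * dy) * 10.0;
        }
      }

      if (hit) {
        // bark (trunk surfaces) carries stronger mottling than other surfaces
        double amp = (hid >= 100 && hid < 200) ? noise_amp_bark : noise_amp;
        val += tex_noise(seed, hid, hu, hv, amp);
      }
      if (val < 0.0) val = 0.0;
      if (val > 255.0) val = 255.0;
      out(row, c) = std::round(val);
    }
  }
  return out;
}

// Mismatch between a reference panorama and every 1-column rotation of a test
// panorama. Rotation r means the test image rotated r degrees clockwise:
// rotate(p, r)[, c] = p[, (c + r) mod W]. SAD returns the raw pixel sum; RMS
// the root of the mean squared difference.
// [[Rcpp::export]]
NumericVector cpp_rotidf(NumericMatrix ref, NumericMatrix test, bool rms) {
  int H = ref.nrow(), W = ref.ncol();
  if (test.nrow() != H || test.ncol() != W)
    stop("reference and test panoramas must have identical dimensions");
  NumericVector out(W);
  const double *pr = REAL(ref), *pt = REAL(test);
  for (int r = 0; r < W; ++r) {
    double s = 0.0;
    for (int c = 0; c < W; ++c) {
      int tc = c + r; if (tc >= W) tc -= W;
      const double *a = pr + (size_t)c * H;
      const double *b = pt + (size_t)tc * H;
      if (rms) {
        for (int i = 0; i < H; ++i) { double d = a[i] - b[i]; s += d * d; }
      } else {
        for (int i = 0; i < H; ++i) s += std::fabs(a[i] - b[i]);
      }
    }
    out[r] = rms ? std::sqrt(s / ((double)H * W)) : s;
  }
  return out;
}
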