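#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of one channel at continuous voxel coordinate (cx, cy, cz).
// Voxel centers sit at index + 0.5 (0-based, half-open cells); outside the
// grid the volume is zero-padded. Codes are stored channel-fastest:
// linear index = ch + nc*(z + nz*(y + ny*x)).
static inline double sample_channel(const int *codes, int nc, int nz, int ny,
                                    int nx, int ch, double cx, double cy,
                                    double cz) {
  double gx = cx - 0.5, gy = cy - 0.5, gz = cz - 0.5;
  int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy),
      z0 = (int)std::floor(gz);
  double fx = gx - x0, fy = gy - y0, fz = gz - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy < 2; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        long idx = ch + (long)nc * (zi + (long)nz * (yi + (long)ny * xi));
        acc += wz * wy * wx * (codes[idx] / 255.0);
      }
    }
  }
  return acc;
}

// Piecewise quadratic transfer: 0 at/below dark, 1 at/above bright,
// clamped quadratic a*v^2 + b*v + c in between.
static inline double eval_transfer(double v, double a, double b, double c,
                                   double dark, double bright) {
  if (v <= dark) return 0.0;
  if (v >= bright) return 1.0;
  double e = a * v * v + b * v + c;
  if (e < 0.0) e = 0.0;
  if (e > 1.0) e = 1.0;
  return e;
}

// Front-to-back multichannel ray march.
//
// codes:      integer volume, dim (nc, nz, ny, nx)
// extents:    world-space box extents (ex, ey, ez); box centered at origin
// origin:     shared ray origin in the volume frame (3)
// dirs:       N x 3 unit ray directions in the volume frame
// t0, t1:     per-ray clipped segment (t1 < t0 => no segment, background)
// tplane:     per-ray plane-intersection parameter (used when plane_mode)
// plane_mode: 1 => single sample exactly at tplane (if inside [t0, t1])
// tf:         nch x 6 matrix: a, b, c, dark, bright, alpha (alpha = 0 when
//             the channel is invisible)
// colors:     nch x 3 channel colors
// step:       world-space sampling step
// term:       early-termination threshold on accumulated alpha
//
// Returns premultiplied accumulated color (N x 3) and alpha (N), i.e. the
// pre-background compositing state.
// [[Rcpp::export(name = ".raycast_core")]]
List raycast_core(IntegerVector codes, IntegerVector cdims,
                  NumericVector extents, NumericVector origin,
                  NumericMatrix dirs, NumericVector t0, NumericVector t1,
                  NumericVector tplane, int plane_mode, NumericMatrix tf,
                  NumericMatrix colors, double step, double term) {
  const int nc = cdims[0], nz = cdims[1], ny = cdims[2], nx = cdims[3];
  const int nray = dirs.nrow();
  const int nch = tf.nrow();
  const double ex = extents[0], ey = extents[1], ez = extents[2];
  const int *cp = INTEGER(codes);

  NumericMatrix out_rgb(nray, 3);
  NumericVector out_a(nray);
  std::vector<double> val(nch);

  for (int r = 0; r < nray; ++r) {
    double a0 = t0[r], a1 = t1[r];
    if (!(a1 >= a0)) continue;
    double ox = origin[0], oy = origin[1], oz = origin[2];
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);

    int nstep;
    double tstart;
    if (plane_mode) {
      double tp = tplane[r];
      if (tp < a0 || tp > a1) continue;
      nstep = 1;
      tstart = tp;
    } else {
      // sample positions t0 + (k + 0.5)*step, k = 0 .. nstep-1, all < t1
      double L = a1 - a0;
      double nd = std::ceil(L / step - 0.5);
      nstep = nd > 0 ? (int)nd : 0;
      tstart = a0 + 0.5 * step;
    }

    double accR = 0, accG = 0, accB = 0, accA = 0;
    for (int k = 0; k < nstep; ++k) {
      double t = plane_mode ? tstart : tstart + k * step;
      double px = ox + t * dx, py = oy + t * dy, pz = oz + t * dz;
      double cx = (px / ex + 0.5) * nx;
      double cy = (py / ey + 0.5) * ny;
      double cz = (pz / ez + 0.5) * nz;

      // per-channel emissive intensities -> union opacity, weighted color
      double one_minus = 1.0, sum_a = 0.0, cR = 0.0, cG = 0.0, cB = 0.0;
      for (int ch = 0; ch < nch; ++ch) {
        double alpha_ch = tf(ch, 5);
        if (alpha_ch <= 0.0) continue;
        double v = sample_channel(cp, nc, nz, ny, nx, ch, cx, cy, cz);
        double e = eval_transfer(v, tf(ch, 0), tf(ch, 1), tf(ch, 2),
                                 tf(ch, 3), tf(ch, 4));
        double ac = e * alpha_ch;
        one_minus *= (1.0 - ac);
        sum_a += ac;
        cR += ac * colors(ch, 0);
        cG += ac * colors(ch, 1);
        cB += ac * colors(ch, 2);
      }
      double as = 1.0 - one_minus;
      if (sum_a > 0.0) {
        cR /= sum_a;
        cG /= sum_a;
        cB /= sum_a;
      }
      // front-to-back over-operator on premultiplied color
      double w = (1.0 - accA) * as;
      accR += w * cR;
      accG += w * cG;
      accB += w * cB;
      accA += w;
      if (accA >= term) break;
    }
    out_rgb(r, 0) = accR;
    out_rgb(r, 1) = accG;
    out_rgb(r, 2) = accB;
    out_a[r] = accA;
  }
  return List::create(_["rgb"] = out_rgb, _["alpha"] = out_a);
}
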