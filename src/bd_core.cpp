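#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Brownian dynamics of point emitters through two co-aligned 3D-Gaussian
// detection volumes centred in a periodic box.
//
// Returns an n_bins x 2 matrix of *expected* photon counts per bin
// (green, red), i.e. the per-step molecular detection rates summed over
// the steps of each bin and multiplied by the step length.  Poisson
// sampling, crosstalk mixing and background are applied by the caller so
// that photon statistics stay in one place.
//
// Randomness: the inner loop burns ~10^9 normal deviates, so it uses a
// private xoshiro256++ stream (Blackman & Vigna) with Marsaglia polar
// normals, seeded from R's RNG by the caller.  Identical R seed =>
// identical seeding vector => identical trajectory.

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  bool have_spare = false;
  double spare = 0.0;

  // Marsaglia polar method
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix bd_expected_counts(int n_bins, int steps_per_bin, double dt,
                                 NumericMatrix pos0,
                                 NumericVector bright_green,
                                 NumericVector bright_red,
                                 NumericVector step_sd,
                                 NumericVector box,
                                 double w0, double z0,
                                 IntegerVector dark0,
                                 NumericVector p_to_dark,
                                 NumericVector p_to_bright,
                                 double rng_seed) {
  const int n = pos0.nrow();
  NumericMatrix out(n_bins, 2);
  if (n == 0) return out;

  const double lx = box[0], ly = box[1], lz = box[2];
  const double cx = lx / 2.0, cy = ly / 2.0, cz = lz / 2.0;
  const double aw = 2.0 / (w0 * w0);   // radial exponent coefficient
  const double az = 2.0 / (z0 * z0);   // axial exponent coefficient

  std::vector<double> x(n), y(n), z(n), bg(n), br(n), sd(n), pd(n), pb(n);
  std::vector<int> dark(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    bg[i] = bright_green[i]; br[i] = bright_red[i];
    sd[i] = step_sd[i]; pd[i] = p_to_dark[i]; pb[i] = p_to_bright[i];
    dark[i] = dark0[i];
  }

  Xoshiro256 rng(static_cast<uint64_t>(rng_seed));
  for (int b = 0; b < n_bins; ++b) {
    double acc_g = 0.0, acc_r = 0.0;
    for (int s = 0; s < steps_per_bin; ++s) {
      for (int i = 0; i < n; ++i) {
        double xi = x[i] + sd[i] * rng.norm();
        double yi = y[i] + sd[i] * rng.norm();
        double zi = z[i] + sd[i] * rng.norm();
        // periodic wrap (single-step displacements are << box edge)
        if (xi < 0) xi += lx; else if (xi >= lx) xi -= lx;
        if (yi < 0) yi += ly; else if (yi >= ly) yi -= ly;
        if (zi < 0) zi += lz; else if (zi >= lz) zi -= lz;
        x[i] = xi; y[i] = yi; z[i] = zi;

        if (pd[i] > 0.0) {
          if (dark[i]) {
            if (rng.unif() < pb[i]) dark[i] = 0;
          } else {
            if (rng.unif() < pd[i]) dark[i] = 1;
          }
          if (dark[i]) continue;
        }

        double dx = xi - cx, dy = yi - cy, dz = zi - cz;
        double e = aw * (dx * dx + dy * dy) + az * dz * dz;
        if (e < 30.0) {       // exp(-30) ~ 1e-13: below any photon budget
          double f = std::exp(-e);
          acc_g += bg[i] * f;
          acc_r += br[i] * f;
        }
      }
    }
    out(b, 0) = acc_g * dt;
    out(b, 1) = acc_r * dt;
  }
  return out;
}
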