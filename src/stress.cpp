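#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fast deterministic stream RNG (xorshift128+ seeded via splitmix64).
// STRESS draws hundreds of millions of spray samples; running them through
// R's RNG dominates the runtime. The stream seed is drawn from R's RNG by
// the R wrapper, so set.seed() still fully determines the output.
struct XorShift128p {
  uint64_t s0, s1;
  explicit XorShift128p(uint64_t seed) {
    // splitmix64 expansion of the seed into two non-zero words
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s0 = z ^ (z >> 31);
    z = seed + 2 * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s1 = z ^ (z >> 31);
    if (!s0 && !s1) s1 = 1;
  }
  inline double next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return ((s1 + y) >> 11) * (1.0 / 9007199254740992.0);  // [0, 1)
  }
};

// STRESS per-channel kernel. For each pixel p0, over N iterations, draw a
// spray of M stochastic samples uniform over the disk of radius R centred at
// p0 (uniformity by rejection sampling in the bounding square; samples
// outside the image are redrawn a bounded number of times, then clamped to
// the border; the centre pixel itself is excluded from the spray). Sample
// extremes include p0, so Emin <= p0 <= Emax by construction. The pixel
// update (p0 - Emin) / (Emax - Emin) reduces to the mean relative value
// v-bar; the zero-range convention returns 1/2.
// [[Rcpp::export(name = ".stress_channel_cpp")]]
NumericMatrix stress_channel_cpp(NumericMatrix ch, double R, int M, int N,
                                 double stream_seed) {
  const int H = ch.nrow(), W = ch.ncol();
  NumericMatrix out(H, W);
  const int max_retry = 20;
  XorShift128p rng((uint64_t) stream_seed);
  const double R2 = R * R;

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double p0 = ch(i, j);
      double rbar = 0.0, vbar = 0.0;
      for (int it = 0; it < N; ++it) {
        double smin = p0, smax = p0;  // index 0 of the sample set is p0
        for (int s = 0; s < M; ++s) {
          int x = -1, y = -1;
          bool ok = false;
          for (int t = 0; t < max_retry; ++t) {
            double dx, dy;
            do {  // uniform over the disk of radius R
              dx = R * (2.0 * rng.next() - 1.0);
              dy = R * (2.0 * rng.next() - 1.0);
            } while (dx * dx + dy * dy > R2);
            x = (int) std::lround(j + dx);
            y = (int) std::lround(i + dy);
            if (x >= 0 && x < W && y >= 0 && y < H && !(x == j && y == i)) {
              ok = true;
              break;
            }
          }
          if (!ok) {
            x = std::min(std::max(x, 0), W - 1);
            y = std::min(std::max(y, 0), H - 1);
            if (x == j && y == i) continue;  // degenerate (e.g. 1x1 image)
          }
          const double v = ch(y, x);
          if (v < smin) smin = v;
          if (v > smax) smax = v;
        }
        const double ri = smax - smin;
        rbar += ri;
        vbar += (ri <= 0.0) ? 0.5 : (p0 - smin) / ri;
      }
      rbar /= N;
      vbar /= N;
      double p;
      if (rbar <= 0.0) {
        p = 0.5;
      } else {
        const double emin = p0 - vbar * rbar;  // Emax = Emin + rbar
        p = (p0 - emin) / rbar;
      }
      out(i, j) = std::min(std::max(p, 0.0), 1.0);
    }
  }
  return out;
}
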