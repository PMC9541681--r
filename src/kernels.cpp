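#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Pairwise Gaussian kernel sums dominate the simulator's runtime, so the two
// O(n * local-neighbourhood) scans live here. Both assume the position
// vectors they search are sorted ascending; the R wrappers take care of that.

static const double INV_SQRT_2PI = 0.39894228040143268;
// contributions beyond 6 units are < 1e-8 per pair and are dropped
static const double KERNEL_CUTOFF = 6.0;

// Density field of Equation-1 form evaluated at each focal point:
// sum_j (1/sqrt(2*pi)) * exp(-(x_f - x_j)^2 / 2) over pos within the cutoff.
// [[Rcpp::export]]
NumericVector kernel_density_sorted(NumericVector focal, NumericVector pos) {
  const int m = focal.size(), n = pos.size();
  NumericVector out(m);
  if (n == 0) return out;
  for (int i = 0; i < m; ++i) {
    const double x = focal[i];
    int j = std::lower_bound(pos.begin(), pos.end(), x - KERNEL_CUTOFF) - pos.begin();
    double s = 0.0;
    for (; j < n && pos[j] <= x + KERNEL_CUTOFF; ++j) {
      const double d = pos[j] - x;
      s += std::exp(-0.5 * d * d);
    }
    out[i] = s * INV_SQRT_2PI;
  }
  return out;
}

// Kernel-weighted mate choice: for each female, pick one male within `radius`
// with probability proportional to exp(-d^2/2) (the 1/sqrt(2*pi) factor
// cancels). Returns the 1-based index into the *sorted* male vector, or 0 when
// no male lies within the radius (the female dies unmated). Uses R's RNG so
// draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector choose_mates_sorted(NumericVector female, NumericVector male_pos,
                                  double radius) {
  const int m = female.size(), n = male_pos.size();
  IntegerVector out(m);
  if (n == 0) return out;
  for (int i = 0; i < m; ++i) {
    const double x = female[i];
    const int lo = std::lower_bound(male_pos.begin(), male_pos.end(), x - radius) -
                   male_pos.begin();
    int hi = lo;
    double tot = 0.0;
    for (int j = lo; j < n && male_pos[j] <= x + radius; ++j) {
      const double d = male_pos[j] - x;
      tot += std::exp(-0.5 * d * d);
      hi = j + 1;
    }
    if (hi == lo || tot <= 0.0) {
      out[i] = 0;
      continue;
    }
    const double u = unif_rand() * tot;
    double acc = 0.0;
    int pick = hi - 1;
    for (int j = lo; j < hi; ++j) {
      const double d = male_pos[j] - x;
      acc += std::exp(-0.5 * d * d);
      if (u <= acc) { pick = j; break; }
    }
    out[i] = pick + 1;
  }
  return out;
}
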