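#include <Rcpp.h>
using namespace Rcpp;

// Three-state kinetic chain R -> A -> I -> R with stimulus-driven R->A rate
// u(t) and constant A->I, I->R rates. Integrated with the trapezoidal
// (Pade 1,1) discretization of the master equation, which conserves total
// occupancy exactly and has the continuous-time stationary distribution as
// its exact fixed point. Rates in 1/s, dt in s.
// [[Rcpp::export]]
NumericMatrix lnk_propagate_cpp(NumericVector u, double k_ai, double k_ir,
                                double dt, NumericVector init) {
  int n = u.size();
  NumericMatrix out(n, 3); // columns R, A, I
  double R = init[0], A = init[1], I = init[2];
  double h = dt / 2.0;
  for (int t = 0; t < n; ++t) {
    double ut = u[t];
    // explicit half-step contribution: (I + h Q) x
    double bR = R + h * (-ut * R + k_ir * I);
    double bA = A + h * (ut * R - k_ai * A);
    double bI = I + h * (k_ai * A - k_ir * I);
    // implicit solve: (I - h Q) x' = b, using R' = S - A' - I' with
    // S = bR + bA + bI (mass conserved).
    double S = bR + bA + bI;
    // equations:
    // A' (1 + h k_ai) - h u R' = bA
    // I' (1 + h k_ir) - h k_ai A' = bI
    // R' = S - A' - I'
    // substitute R':
    // A' (1 + h k_ai + h u) + h u I' = bA + h u S
    double a11 = 1.0 + h * k_ai + h * ut, a12 = h * ut;
    double a21 = -h * k_ai, a22 = 1.0 + h * k_ir;
    double r1 = bA + h * ut * S, r2 = bI;
    double det = a11 * a22 - a12 * a21;
    A = (r1 * a22 - a12 * r2) / det;
    I = (a11 * r2 - a21 * r1) / det;
    R = S - A - I;
    out(t, 0) = R; out(t, 1) = A; out(t, 2) = I;
  }
  return out;
}

inline double softplus_c(double g) {
  return g > 30.0 ? g : std::log1p(std::exp(g));
}

// Poisson spike generation with a causal spike-history term: per 1-bin
// step, rate = softplus(g_stim[t] + (h * past spikes)[t] - theta); each
// emitted count feeds the history of future bins. Uses R's RNG (seeded via
// set.seed). Returns an integer matrix bins x repeats.
// [[Rcpp::export]]
IntegerMatrix simulate_spikes_cpp(NumericVector gstim, NumericVector hkern,
                                  double theta, int n_repeats,
                                  double rate_floor) {
  int n = gstim.size(), L = hkern.size();
  IntegerMatrix out(n, n_repeats);
  std::vector<double> gbuf(n);
  for (int r = 0; r < n_repeats; ++r) {
    for (int t = 0; t < n; ++t) gbuf[t] = gstim[t];
    for (int t = 0; t < n; ++t) {
      double rate = softplus_c(gbuf[t] - theta);
      if (rate < rate_floor) rate = rate_floor;
      int cnt = (int) R::rpois(rate);
      if (cnt > 0) {
        out(t, r) = cnt;
        int lmax = std::min(L, n - t - 1);
        for (int l = 0; l < lmax; ++l)
          gbuf[t + 1 + l] += cnt * hkern[l];
      }
    }
  }
  return out;
}

// Causal convolution of a count series with a history kernel, lag 1..L
// (no self-bin): out[t] = sum_l h[l] * counts[t - l].
// [[Rcpp::export]]
NumericVector history_conv_cpp(IntegerVector counts, NumericVector hkern) {
  int n = counts.size(), L = hkern.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    if (counts[t] > 0) {
      int lmax = std::min(L, n - t - 1);
      for (int l = 0; l < lmax; ++l)
        out[t + 1 + l] += counts[t] * hkern[l];
    }
  }
  return out;
}

// Piecewise-linear interpolation on a tent basis: values and segment
// slopes, clamped outside the knot range (value constant, slope zero).
// [[Rcpp::export]]
List tent_interp_cpp(NumericVector knots, NumericVector w, NumericVector x,
                     bool want_deriv) {
  int K = knots.size(), n = x.size();
  NumericVector val(n), der(want_deriv ? n : 0);
  double k0 = knots[0], kK = knots[K - 1];
  for (int t = 0; t < n; ++t) {
    double xi = x[t];
    bool out = (xi < k0) || (xi > kK);
    double xc = out ? (xi < k0 ? k0 : kK) : xi;
    // binary search for interval [knots[i], knots[i+1])
    int lo = 0, hi = K - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (knots[mid] <= xc) lo = mid; else hi = mid;
    }
    double h = knots[lo + 1] - knots[lo];
    double u = (xc - knots[lo]) / h;
    val[t] = w[lo] * (1.0 - u) + w[lo + 1] * u;
    if (want_deriv) der[t] = out ? 0.0 : (w[lo + 1] - w[lo]) / h;
  }
  if (want_deriv) return List::create(_["value"] = val, _["deriv"] = der);
  return List::create(_["value"] = val);
}
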