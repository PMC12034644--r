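#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Batch evaluation of the four-muscle Hill-type knee model.
//
// L:   pop x 26 chromosome matrix in the canonical parameter order
//      [A, dW_asc, v_asc, dW_des, v_dec, eps0, then per muscle
//       (lo, phi, fo, qv, lt)].
// lmt, vmt, u, r: n x 4 per-sample series (muscle order BF, RF, VL, VM).
// sgn: +1 flexor, -1 extensor.
//
// Returns a pop x n matrix of knee torques. Semantics mirror the reference
// R implementation: degenerate geometry floors the along-tendon span at 0
// and the fiber length at 1e-6*lo; the concentric force-velocity branch is
// clamped at 0, the eccentric at 1.8; passive force uses expm1 of the
// clamped strain.
// [[Rcpp::export]]
NumericMatrix forward_torque_core(NumericMatrix L, NumericMatrix lmt,
                                  NumericMatrix vmt, NumericMatrix u,
                                  NumericMatrix r, NumericVector sgn,
                                  double kpe) {
  const int pop = L.nrow();
  const int n = lmt.nrow();
  NumericMatrix tau(pop, n);
  const double ekpe = std::expm1(kpe);

  for (int p = 0; p < pop; ++p) {
    double A = L(p, 0);
    if (std::fabs(A) < 1e-9) A = 1e-9;   // identity limit of the activation map
    const double eA = std::expm1(A);
    const double dWa = L(p, 1), va = L(p, 2);
    const double dWd = L(p, 3), vd = L(p, 4), e0 = L(p, 5);

    for (int i = 0; i < 4; ++i) {
      const int off = 6 + i * 5;
      const double lo = L(p, off), phi = L(p, off + 1), fo = L(p, off + 2);
      const double qv = L(p, off + 3), lt = L(p, off + 4);
      const double h2 = lo * std::sin(phi) * lo * std::sin(phi);
      const double lm_floor = 1e-6 * lo;
      const double s = sgn[i];

      for (int t = 0; t < n; ++t) {
        double dx = lmt(t, i) - lt;
        if (dx < 0) dx = 0;
        double lm = std::sqrt(dx * dx + h2);
        if (lm < lm_floor) lm = lm_floor;
        const double cphi = dx / lm;
        const double lbar = lm / lo;
        const double vbar = cphi * vmt(t, i) / (qv * lo);

        const double a = std::expm1(A * u(t, i)) / eA;

        const double d = std::fabs(lbar - 1.0);
        const double fl = (lbar <= 1.0) ? std::exp(-std::pow(d / dWa, va))
                                        : std::exp(-std::pow(d / dWd, vd));

        double fv;
        if (vbar <= 0) {
          fv = 0.3 * (vbar + 1.0) / (0.3 - vbar);
          if (fv < 0) fv = 0;
        } else {
          fv = (2.34 * vbar + 0.039) / (1.3 * vbar + 0.039);
          if (fv > 1.8) fv = 1.8;
        }

        // passive curve: exponential toe up to the maximum strain e0, then
        // linear (tangent) continuation to keep extreme chromosomes finite
        const double strain = lbar > 1.0 ? (lbar - 1.0) : 0.0;
        double fpe;
        if (strain <= e0) {
          fpe = std::expm1(kpe * strain / e0) / ekpe;
        } else {
          fpe = 1.0 + kpe * std::exp(kpe) / (e0 * ekpe) * (strain - e0);
        }

        tau(p, t) += s * fo * (fl * fv * a + fpe) * cphi * r(t, i);
      }
    }
  }
  return tau;
}
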