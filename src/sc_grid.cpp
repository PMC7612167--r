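#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Evaluate a grid of (theta_f, theta_e) curtailment-threshold pairs for a
// fixed (r, N, B), returning the feasible designs only.
//
// For each pair the conditional-power table is rebuilt by the backward
// recursion (thresholding is applied block-by-block, so rounded values feed
// the sums of earlier blocks) and the operating characteristics follow from
// forward first-passage recursions under the null and alternative
// anticipated rates.  The accumulation order of every sum matches the pure-R
// implementation so that state classification agrees exactly.
//
// pmf_design: block success pmf at (p0, p1) (drives the recursion and the
//             alternative-rates forward pass)
// pmf_null:   block success pmf at (p0, p0)
// theta_f, theta_e: candidate threshold values; all pairs with f < e are
//             evaluated
// [[Rcpp::export]]
DataFrame sc_grid_eval_cpp(int r, int N, int B,
                           NumericVector pmf_design, NumericVector pmf_null,
                           NumericVector theta_f, NumericVector theta_e,
                           double alpha, double beta) {
  const int M = N / 2;
  const int nb = M / B;
  const int K = 2 * B;

  std::vector<std::vector<double> > cp(nb);
  for (int j = 0; j < nb; ++j) cp[j].resize(2 * (j + 1) * B + 1);
  std::vector<double> w(2 * M + 1), nxt(2 * M + 1);

  std::vector<double> out_tf, out_te, out_a, out_pw, out_e00, out_e01;

  for (int fi = 0; fi < theta_f.size(); ++fi) {
    const double tF = theta_f[fi];
    for (int ei = 0; ei < theta_e.size(); ++ei) {
      const double tE = theta_e[ei];
      if (!(tF < tE)) continue;

      // backward pass
      {
        std::vector<double>& base = cp[nb - 1];
        for (int s = 0; s <= 2 * M; ++s) base[s] = (s >= M + r + 1) ? 1.0 : 0.0;
      }
      for (int j = nb - 2; j >= 0; --j) {
        const int m = (j + 1) * B;
        const std::vector<double>& nx = cp[j + 1];
        std::vector<double>& cur = cp[j];
        for (int s = 0; s <= 2 * m; ++s) {
          double D = 0.0;
          for (int i = 0; i <= K; ++i) D += pmf_design[i] * nx[s + i];
          double v = D;
          if (D < tF) v = 0.0;
          if (D > tE) v = 1.0;
          if (2 * m - s >= M - r) v = 0.0;
          if (s >= M + r + 1) v = 1.0;
          cur[s] = v;
        }
      }

      // forward pass at (p0, p0)
      double ess00 = 0.0, a_star = 0.0;
      for (int s = 0; s <= K; ++s) w[s] = pmf_null[s];
      for (int j = 0; j < nb; ++j) {
        const int m = (j + 1) * B;
        const std::vector<double>& cur = cp[j];
        double pstop = 0.0;
        for (int s = 0; s <= 2 * m; ++s) {
          const double v = cur[s];
          if (v == 0.0 || v == 1.0) {
            pstop += w[s];
            if (v == 1.0) a_star += w[s];
          }
        }
        ess00 += 2.0 * m * pstop;
        if (j < nb - 1) {
          const int len = 2 * (m + B);
          for (int s = 0; s <= len; ++s) nxt[s] = 0.0;
          for (int i = 0; i <= K; ++i)
            for (int s = 0; s <= 2 * m; ++s) {
              const double v = cur[s];
              if (v > 0.0 && v < 1.0) nxt[s + i] += w[s] * pmf_null[i];
            }
          for (int s = 0; s <= len; ++s) w[s] = nxt[s];
        }
      }
      if (a_star > alpha) continue;

      // forward pass at (p0, p1)
      double ess01 = 0.0, power = 0.0;
      for (int s = 0; s <= K; ++s) w[s] = pmf_design[s];
      for (int j = 0; j < nb; ++j) {
        const int m = (j + 1) * B;
        const std::vector<double>& cur = cp[j];
        double pstop = 0.0;
        for (int s = 0; s <= 2 * m; ++s) {
          const double v = cur[s];
          if (v == 0.0 || v == 1.0) {
            pstop += w[s];
            if (v == 1.0) power += w[s];
          }
        }
        ess01 += 2.0 * m * pstop;
        if (j < nb - 1) {
          const int len = 2 * (m + B);
          for (int s = 0; s <= len; ++s) nxt[s] = 0.0;
          for (int i = 0; i <= K; ++i)
            for (int s = 0; s <= 2 * m; ++s) {
              const double v = cur[s];
              if (v > 0.0 && v < 1.0) nxt[s + i] += w[s] * pmf_design[i];
            }
          for (int s = 0; s <= len; ++s) w[s] = nxt[s];
        }
      }
      if (power < 1.0 - beta) continue;

      out_tf.push_back(tF);
      out_te.push_back(tE);
      out_a.push_back(a_star);
      out_pw.push_back(power);
      out_e00.push_back(ess00);
      out_e01.push_back(ess01);
    }
    Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(_["theta_f"] = out_tf, _["theta_e"] = out_te,
                           _["alpha_star"] = out_a, _["power"] = out_pw,
                           _["ess00"] = out_e00, _["ess01"] = out_e01);
}
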