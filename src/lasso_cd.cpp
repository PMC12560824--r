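#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic coordinate descent over a decreasing lambda path with warm starts
// and a KKT-guided active set, on the Gram form of the standardized problem:
// minimize 0.5*b'Gb - c'b + lambda*||b||_1 with G[j][j] == 1, so each
// coordinate update is an exact soft threshold. A per-lambda sweep cap
// bounds the work where the minimizer is non-unique (p > n, tiny lambda).
//
// [[Rcpp::export]]
NumericMatrix lasso_cd_path(const NumericMatrix& G, const NumericVector& cvec,
                            const NumericVector& lambdas_desc,
                            double tol, int max_sweeps) {
  const int p = G.ncol();
  const int L = lambdas_desc.size();
  NumericMatrix out(p, L);
  std::vector<double> b(p, 0.0), Gb(p, 0.0);
  std::vector<int> act;
  act.reserve(p);

  for (int li = 0; li < L; ++li) {
    const double lam = lambdas_desc[li];
    int sweeps = 0;
    while (true) {
      act.clear();
      for (int j = 0; j < p; ++j) {
        if (b[j] != 0.0 || std::fabs(cvec[j] - Gb[j]) > lam + 1e-12)
          act.push_back(j);
      }
      if (act.empty()) break;
      bool converged = false;
      while (sweeps < max_sweeps) {
        ++sweeps;
        double max_change = 0.0;
        for (size_t a = 0; a < act.size(); ++a) {
          const int j = act[a];
          const double rho = cvec[j] - Gb[j] + b[j];
          double bj = 0.0;
          if (rho > lam) bj = rho - lam;
          else if (rho < -lam) bj = rho + lam;
          if (bj != b[j]) {
            const double delta = bj - b[j];
            const double* Gcol = &G(0, j);
            for (int k = 0; k < p; ++k) Gb[k] += Gcol[k] * delta;
            b[j] = bj;
            const double ad = std::fabs(delta);
            if (ad > max_change) max_change = ad;
          }
        }
        if (max_change < tol) { converged = true; break; }
      }
      if (!converged) break;  // sweep budget exhausted; accept current point
      bool kkt_ok = true;
      for (int j = 0; j < p; ++j) {
        if (b[j] == 0.0 && std::fabs(cvec[j] - Gb[j]) > lam + 1e-10) {
          kkt_ok = false;
          break;
        }
      }
      if (kkt_ok) break;
    }
    for (int j = 0; j < p; ++j) out(j, li) = b[j];
  }
  return out;
}
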