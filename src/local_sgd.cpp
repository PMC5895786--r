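#include <Rcpp.h>
using namespace Rcpp;

// One Nesterov-accelerated Adam update of a scalar parameter.
// m, v are the block's first/second moment entries for this coordinate,
// updated in place. prod_after = running product of beta1 schedule values
// up to and including the current step t; bc2 = 1 - beta2^t.
static inline double nadam_dir(double &m, double &v, double g,
                               double beta1_t, double beta1_next,
                               double prod_after, double beta2,
                               double bc2, double eps) {
  m = beta1_t * m + (1.0 - beta1_t) * g;
  v = beta2 * v + (1.0 - beta2) * g * g;
  double d1 = 1.0 - prod_after;
  double d1n = 1.0 - prod_after * beta1_next;
  if (d1 < 1e-300) d1 = 1e-300;
  if (d1n < 1e-300) d1n = 1e-300;
  double ghat = g / d1;
  double mhat = m / d1n;
  double vhat = v / bc2;
  return (beta1_next * mhat + (1.0 - beta1_t) * ghat) / (std::sqrt(vhat) + eps);
}

// Local SGD over one partition's training entries. All parameter and
// moment arrays are modified in place (the R wrapper passes copies where
// copy semantics are required). Entry indices are 0-based; ei indexes
// rows of G/gb (partition-local). Random entry sampling uses R's RNG so
// a set.seed() in the caller makes the pass reproducible; sequential=true
// instead walks the entries in the given order (used for epoch passes).
// [[Rcpp::export]]
List local_sgd_cpp(NumericMatrix C, NumericVector cb,
                   NumericMatrix A, NumericVector ab,
                   NumericMatrix G, NumericVector gb,
                   IntegerVector ej, IntegerVector ek, IntegerVector ei,
                   NumericVector ed,
                   int n_iters, bool sequential,
                   bool update_shared, bool update_genome,
                   NumericMatrix mC, NumericMatrix vC,
                   NumericVector mc, NumericVector vc,
                   NumericMatrix mA, NumericMatrix vA,
                   NumericVector ma, NumericVector va,
                   NumericMatrix mG, NumericMatrix vG,
                   NumericVector mg, NumericVector vg,
                   double tCA, double tG, double prodCA, double prodG,
                   double eta, double phi_eta, double beta1, double phi_beta1,
                   double beta2, double eps,
                   double lamC, double lamA, double lamG,
                   NumericVector nC, NumericVector nA, NumericVector nG) {
  const int L = C.ncol();
  const int n_entries = ej.size();
  if (n_entries == 0 || n_iters <= 0)
    return List::create(_["tCA"] = tCA, _["tG"] = tG,
                        _["prodCA"] = prodCA, _["prodG"] = prodG);
  std::vector<double> xc(L), xa(L), xg(L);
  for (int it = 0; it < n_iters; ++it) {
    int idx;
    if (sequential) {
      idx = it % n_entries;
    } else {
      idx = (int)(unif_rand() * n_entries);
      if (idx >= n_entries) idx = n_entries - 1;
    }
    const int j = ej[idx], k = ek[idx], i = ei[idx];
    const double d = ed[idx];

    double pred = cb[j] + ab[k] + gb[i];
    for (int l = 0; l < L; ++l) {
      xc[l] = C(j, l); xa[l] = A(k, l); xg[l] = G(i, l);
      pred += xc[l] * xa[l] * xg[l];
    }
    const double e = pred - d;
    const double twoe = 2.0 * e;

    if (update_shared) {
      const double t = tCA + 1.0;
      const double eta_t = eta * std::pow(phi_eta, t - 1.0);
      const double b1t = beta1 * std::pow(phi_beta1, t - 1.0);
      const double b1n = beta1 * std::pow(phi_beta1, t);
      const double prod_after = prodCA * b1t;
      const double bc2 = 1.0 - std::pow(beta2, t);
      const double rc = 2.0 * lamC / nC[j];
      const double ra = 2.0 * lamA / nA[k];
      for (int l = 0; l < L; ++l) {
        double gradC = twoe * xa[l] * xg[l] + rc * xc[l];
        C(j, l) -= eta_t * nadam_dir(mC(j, l), vC(j, l), gradC,
                                     b1t, b1n, prod_after, beta2, bc2, eps);
        double gradA = twoe * xc[l] * xg[l] + ra * xa[l];
        A(k, l) -= eta_t * nadam_dir(mA(k, l), vA(k, l), gradA,
                                     b1t, b1n, prod_after, beta2, bc2, eps);
      }
      cb[j] -= eta_t * nadam_dir(mc[j], vc[j], twoe,
                                 b1t, b1n, prod_after, beta2, bc2, eps);
      ab[k] -= eta_t * nadam_dir(ma[k], va[k], twoe,
                                 b1t, b1n, prod_after, beta2, bc2, eps);
      tCA = t;
      prodCA = prod_after;
    }
    if (update_genome) {
      const double t = tG + 1.0;
      const double eta_t = eta * std::pow(phi_eta, t - 1.0);
      const double b1t = beta1 * std::pow(phi_beta1, t - 1.0);
      const double b1n = beta1 * std::pow(phi_beta1, t);
      const double prod_after = prodG * b1t;
      const double bc2 = 1.0 - std::pow(beta2, t);
      const double rg = 2.0 * lamG / nG[i];
      for (int l = 0; l < L; ++l) {
        double gradG = twoe * xc[l] * xa[l] + rg * xg[l];
        G(i, l) -= eta_t * nadam_dir(mG(i, l), vG(i, l), gradG,
                                     b1t, b1n, prod_after, beta2, bc2, eps);
      }
      gb[i] -= eta_t * nadam_dir(mg[i], vg[i], twoe,
                                 b1t, b1n, prod_after, beta2, bc2, eps);
      tG = t;
      prodG = prod_after;
    }
  }
  return List::create(_["tCA"] = tCA, _["tG"] = tG,
                      _["prodCA"] = prodCA, _["prodG"] = prodG);
}
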