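// Two-locus haplotype-frequency EM over genotype likelihoods.
//
// Haplotypes indexed 0..3 as (allele at site 1, allele at site 2) with
// 0 = major, 1 = minor: 0 = AB, 1 = Ab, 2 = aB, 3 = ab. Individuals are
// random unions of two gametes; the likelihood of an individual is
//   sum_{j<=k} (2 - [j==k]) h_j h_k L1(g1(j,k)) L2(g2(j,k))
// with g1, g2 the summed alleles. The E-step accumulates expected
// haplotype counts; the M-step renormalises. This is the hot loop of the
// whole-chromosome LD scan, hence C++.

#include <Rcpp.h>
using namespace Rcpp;

static const int A1[4] = {0, 0, 1, 1};  // minor-allele dose at site 1
static const int A2[4] = {0, 1, 0, 1};  // minor-allele dose at site 2

// One pair EM. l1x, l2x: N x 3 (columns: 0,1,2 minor copies).
// Results written into out[0..8]: hAB hAb haB hab D Dprime r2 f1 f2.
// If trace != nullptr, per-iteration log-likelihood is appended.
static void pair_em_core(const double* l1, const double* l2, int n,
                         int max_iter, double tol, double* out,
                         std::vector<double>* trace) {
  double h[4] = {0.25, 0.25, 0.25, 0.25};
  double cnt[4];
  for (int it = 0; it < max_iter; ++it) {
    cnt[0] = cnt[1] = cnt[2] = cnt[3] = 0.0;
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double wsum = 0.0, wc[4] = {0, 0, 0, 0};
      for (int j = 0; j < 4; ++j) {
        for (int k = j; k < 4; ++k) {
          int g1 = A1[j] + A1[k], g2 = A2[j] + A2[k];
          double lik = l1[i + n * g1] * l2[i + n * g2];
          double w = (j == k ? 1.0 : 2.0) * h[j] * h[k] * lik;
          wsum += w;
          wc[j] += w;
          wc[k] += w;
        }
      }
      if (wsum <= 0.0) continue;  // uninformative individual
      for (int j = 0; j < 4; ++j) cnt[j] += wc[j] / wsum;
      ll += std::log(wsum);
    }
    if (trace) trace->push_back(ll);
    double tot = cnt[0] + cnt[1] + cnt[2] + cnt[3];
    if (tot <= 0.0) break;
    double delta = 0.0;
    for (int j = 0; j < 4; ++j) {
      double hn = cnt[j] / tot;
      delta = std::max(delta, std::fabs(hn - h[j]));
      h[j] = hn;
    }
    if (delta < tol) break;
  }
  double f1 = h[2] + h[3];  // minor freq at site 1
  double f2 = h[1] + h[3];  // minor freq at site 2
  double D = h[3] - f1 * f2;
  double denom = f1 * (1 - f1) * f2 * (1 - f2);
  double r2 = 0.0, dprime = 0.0;
  if (denom > 1e-12) {
    r2 = D * D / denom;
    double dmax = D >= 0 ? std::min(f1 * (1 - f2), (1 - f1) * f2)
                         : std::min(f1 * f2, (1 - f1) * (1 - f2));
    if (dmax > 1e-12) dprime = D / dmax;
  }
  out[0] = h[0]; out[1] = h[1]; out[2] = h[2]; out[3] = h[3];
  out[4] = D; out[5] = dprime; out[6] = r2; out[7] = f1; out[8] = f2;
}

// [[Rcpp::export(name = ".pair_ld_single")]]
List pair_ld_single(NumericMatrix gl1, NumericMatrix gl2,
                    int max_iter = 500, double tol = 1e-8,
                    bool track_loglik = false) {
  int n = gl1.nrow();
  if (gl2.nrow() != n) stop("likelihood matrices differ in rows");
  std::vector<double> trace;
  double out[9];
  pair_em_core(REAL(gl1), REAL(gl2), n, max_iter, tol, out,
               track_loglik ? &trace : nullptr);
  List res = List::create(
    _["h"] = NumericVector::create(out[0], out[1], out[2], out[3]),
    _["D"] = out[4], _["Dprime"] = out[5], _["r2"] = out[6],
    _["f1"] = out[7], _["f2"] = out[8]);
  if (track_loglik) res["trace"] = wrap(trace);
  return res;
}

// Batch r^2 for many site pairs. l0, l1, l2: S x N likelihood layers;
// ia, ib: 1-based site indices per pair.
// [[Rcpp::export(name = ".pair_ld_batch")]]
NumericMatrix pair_ld_batch(NumericMatrix l0, NumericMatrix l1,
                            NumericMatrix l2, IntegerVector ia,
                            IntegerVector ib, int max_iter = 500,
                            double tol = 1e-8) {
  int s = l0.nrow(), n = l0.ncol(), np = ia.size();
  if (ib.size() != np) stop("pair index vectors differ in length");
  NumericMatrix res(np, 5);  // r2, D, Dprime, f1, f2
  std::vector<double> g1(n * 3), g2(n * 3);
  const double* p0 = REAL(l0);
  const double* p1 = REAL(l1);
  const double* p2 = REAL(l2);
  double out[9];
  for (int p = 0; p < np; ++p) {
    int a = ia[p] - 1, b = ib[p] - 1;
    if (a < 0 || a >= s || b < 0 || b >= s) stop("pair index out of range");
    for (int i = 0; i < n; ++i) {
      g1[i] = p0[a + s * i]; g1[i + n] = p1[a + s * i]; g1[i + 2 * n] = p2[a + s * i];
      g2[i] = p0[b + s * i]; g2[i + n] = p1[b + s * i]; g2[i + 2 * n] = p2[b + s * i];
    }
    pair_em_core(g1.data(), g2.data(), n, max_iter, tol, out, nullptr);
    res(p, 0) = out[6]; res(p, 1) = out[4]; res(p, 2) = out[5];
    res(p, 3) = out[7]; res(p, 4) = out[8];
  }
  colnames(res) = CharacterVector::create("r2", "D", "Dprime", "f1", "f2");
  return res;
}
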