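#include <Rcpp.h>
using namespace Rcpp;

// Weighted M-step objective for one shifted negative binomial component:
//   sum_t wt_t * log( sum_x T[t,x] f(x) / sum_x D(x) f(x) )
// with f(x) = dnbinom(x - 1; size = r, mu = mp) evaluated by the one-term
// recurrence.  T is the CSC sparse tract-function matrix (tracts x X_max).
// The scan stops once the remaining upper-tail mass is below 1e-13 and all
// weighted tract spans are covered (span_need).  Returns -1e12 when the
// parameters cannot be scored faithfully: pmf underflow at the origin,
// > 10% of the mass beyond the table, or a weighted tract with zero
// probability.
// [[Rcpp::export]]
double mstep_obj_cpp(double mp, double r, S4 Tmat, NumericVector D,
                NumericVector wt, double span_need) {
  IntegerVector Ti = Tmat.slot("i");
  NumericVector Tx = Tmat.slot("x");
  IntegerVector Tp = Tmat.slot("p");
  IntegerVector dims = Tmat.slot("Dim");
  const int ntr = dims[0];
  const int X = dims[1];
  const int* ti = INTEGER(Ti);
  const double* tx = REAL(Tx);
  const int* tp = INTEGER(Tp);
  const double* d = REAL(D);
  const double* w = REAL(wt);
  std::vector<double> numer(ntr, 0.0);
  const double pr = mp / (r + mp);
  double f = std::exp(r * std::log1p(-pr));
  if (f <= 0.0) return -1e12;
  double denom = 0.0, mass = 0.0;
  for (int x = 1; x <= X; ++x) {
    if (f > 0.0) {
      denom += d[x - 1] * f;
      mass += f;
      for (int idx = tp[x - 1]; idx < tp[x]; ++idx)
        numer[ti[idx]] += tx[idx] * f;
    }
    if (x >= span_need && (1.0 - mass) < 1e-13) break;
    f *= (r + x - 1.0) / x * pr;
  }
  if (mass < 0.9 || denom <= 0.0) return -1e12;
  const double ld = std::log(denom);
  double obj = 0.0;
  for (int t = 0; t < ntr; ++t)
    if (w[t] > 0.0) {
      if (numer[t] <= 0.0) return -1e12;
      obj += w[t] * (std::log(numer[t]) - ld);
    }
  return obj;
}
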