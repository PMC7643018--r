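#include <Rcpp.h>
using namespace Rcpp;

// Fused Adam update for one parameter tensor: returns new (w, m, v).
// Bias corrections are folded into the step size `a` by the caller.
// Raw REAL() pointers: the hot loop runs once per minibatch per tensor.
// [[Rcpp::export(rng = false)]]
List adam_fused(SEXP w, SEXP m, SEXP v, SEXP g,
                double a, double b1, double b2, double eps) {
  R_xlen_t n = XLENGTH(w);
  SEXP w2 = PROTECT(Rf_allocVector(REALSXP, n));
  SEXP m2 = PROTECT(Rf_allocVector(REALSXP, n));
  SEXP v2 = PROTECT(Rf_allocVector(REALSXP, n));
  const double *pw = REAL(w), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  double *qw = REAL(w2), *qm = REAL(m2), *qv = REAL(v2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    double mi = b1 * pm[i] + (1.0 - b1) * gi;
    double vi = b2 * pv[i] + (1.0 - b2) * gi * gi;
    qm[i] = mi;
    qv[i] = vi;
    qw[i] = pw[i] - a * mi / (std::sqrt(vi) + eps);
  }
  DUPLICATE_ATTRIB(w2, w);
  List out = List::create(w2, m2, v2);
  UNPROTECT(3);
  return out;
}

// Elementwise rectifier, new vector (keeps dim attribute).
// [[Rcpp::export(rng = false)]]
SEXP relu_fwd(SEXP z) {
  R_xlen_t n = XLENGTH(z);
  SEXP out = PROTECT(Rf_allocVector(REALSXP, n));
  const double *pz = REAL(z);
  double *po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) po[i] = pz[i] > 0.0 ? pz[i] : 0.0;
  DUPLICATE_ATTRIB(out, z);
  UNPROTECT(1);
  return out;
}

// Gradient gate of the rectifier: dZ = dA * (Z > 0).
// [[Rcpp::export(rng = false)]]
SEXP relu_bwd(SEXP da, SEXP z) {
  R_xlen_t n = XLENGTH(z);
  SEXP out = PROTECT(Rf_allocVector(REALSXP, n));
  const double *pz = REAL(z), *pd = REAL(da);
  double *po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) po[i] = pz[i] > 0.0 ? pd[i] : 0.0;
  DUPLICATE_ATTRIB(out, da);
  UNPROTECT(1);
  return out;
}
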