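#include <Rcpp.h>
using namespace Rcpp;

// Continuity (FC) and bending (FE) inner evaluation for one spatial scale,
// given the lobe maps O (npix x nray matrix; ray = channel/sense pair).
//
// FC: per ray r, ending mass Ee = O[, ee_idx[r]], originating mass
// E = max over candidate columns cand(r, ); contributes
// ramp(Ee - E) - ramp(-E) per pixel, with ramp the Gaussian-smoothed ramp
// of width sigR.  Since the ramp is increasing and Ee >= 0, every term is
// non-negative; it vanishes when Ee = 0 (nothing ends, so originating mass
// alone earns nothing) and approaches Ee when an ending has no
// continuation.  FE: per pair, w * sum(O[, gi] * O[, go]).
//
// With grad = true also accumulates d(total)/dO with the caller-supplied
// absolute weights wC and wE folded in.
// [[Rcpp::export]]
List fcfe_eval(const NumericMatrix& O, const NumericMatrix& Fof,
               const IntegerMatrix& cand, const NumericMatrix& cgam,
               const IntegerVector& ee_idx,
               const IntegerVector& fe_gi, const IntegerVector& fe_go,
               const NumericVector& fe_w, double sigR, double epsC,
               double wC, double wE, bool grad) {
  const int npix = O.nrow(), nray = O.ncol(), ncand = cand.ncol();
  double fc = 0.0, fe = 0.0;
  NumericMatrix dO;
  if (grad) dO = NumericMatrix(npix, nray);
  std::vector<double> E(npix);
  std::vector<int> amax(npix);
  for (int r = 0; r < nray; ++r) {
    const double* Ee = &O(0, ee_idx[r] - 1);
    // running max over candidates; the off-canvas lobe fraction counts as
    // continuation at the ending's own strength
    {
      const double* c0 = &O(0, cand(r, 0) - 1);
      const double* f0 = &Fof(0, cand(r, 0) - 1);
      const double g0 = cgam(r, 0);
      for (int i = 0; i < npix; ++i) {
        E[i] = g0 * c0[i] + f0[i] * Ee[i];
        amax[i] = 0;
      }
      for (int c = 1; c < ncand; ++c) {
        const double* cc = &O(0, cand(r, c) - 1);
        const double* fc_ = &Fof(0, cand(r, c) - 1);
        const double gc = cgam(r, c);
        for (int i = 0; i < npix; ++i) {
          const double v = gc * cc[i] + fc_[i] * Ee[i];
          if (v > E[i]) { E[i] = v; amax[i] = c; }
        }
      }
    }
    for (int i = 0; i < npix; ++i) {
      const double x = Ee[i] - E[i];
      const double u = x / sigR;
      const double um = -E[i] / sigR;
      const double Phi = R::pnorm(u, 0.0, 1.0, 1, 0);
      const double Phim = R::pnorm(um, 0.0, 1.0, 1, 0);
      const double ramp = x * Phi + sigR * R::dnorm(u, 0.0, 1.0, 0)
          - (-E[i] * Phim + sigR * R::dnorm(um, 0.0, 1.0, 0));
      const double d2 = Ee[i] * Ee[i] + epsC * epsC;
      const double S = Ee[i] * Ee[i] / d2;            // soft ending gate
      fc += S * ramp;
      if (grad) {
        const double dS = 2.0 * Ee[i] * epsC * epsC / (d2 * d2);
        const double dE = wC * S * (Phim - Phi);   // d cost / d E
        dO(i, ee_idx[r] - 1) += wC * (dS * ramp + S * Phi)
          + dE * Fof(i, cand(r, amax[i]) - 1);
        dO(i, cand(r, amax[i]) - 1) += dE * cgam(r, amax[i]);
      }
    }
  }
  for (int k = 0; k < fe_w.size(); ++k) {
    const double* Oi = &O(0, fe_gi[k] - 1);
    const double* Oo = &O(0, fe_go[k] - 1);
    const double w = fe_w[k];
    double acc = 0.0;
    for (int i = 0; i < npix; ++i) acc += Oi[i] * Oo[i];
    fe += w * acc;
    if (grad) {
      double* dgi = &dO(0, fe_gi[k] - 1);
      double* dgo = &dO(0, fe_go[k] - 1);
      const double ww = wE * w;
      for (int i = 0; i < npix; ++i) {
        dgi[i] += ww * Oo[i];
        dgo[i] += ww * Oi[i];
      }
    }
  }
  List out = List::create(_["fc"] = fc, _["fe"] = fe);
  if (grad) out["dO"] = dO;
  return out;
}
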