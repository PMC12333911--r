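#include <Rcpp.h>
using namespace Rcpp;

// Leave-one-out Aalen-Johansen CIF for one cause, evaluated on a sorted grid.
//
// ut     : J distinct event times (sorted, any cause)
// dmat   : J x K unweighted event counts per cause
// dtot   : J all-cause event counts (rowSums of dmat)
// nrisk  : J unweighted at-risk counts at ut[j]-
// lt     : per subject, #{ut <= T*_i} (subject at risk at ut[j] iff j < lt[i], 0-based)
// own    : per subject, 1-based index of own event time in ut (0 if censored)
// status : per subject, 0..K
// cause  : cause of interest (1-based)
// gidx   : per grid time (ascending), #{ut <= t_g}
//
// Returns n x G matrix of I_k^{(-i)}(t_g).
// [[Rcpp::export]]
NumericMatrix loo_cif_kernel(NumericVector ut, IntegerMatrix dmat,
                             IntegerVector dtot, IntegerVector nrisk,
                             IntegerVector lt, IntegerVector own,
                             IntegerVector status, int cause,
                             IntegerVector gidx) {
  const int J = ut.size(), n = lt.size(), G = gidx.size();
  NumericMatrix out(n, G);
  const int kc = cause - 1;
  const int *dk_col = &dmat(0, kc), *dt = &dtot[0], *nr = &nrisk[0];
  for (int i = 0; i < n; ++i) {
    double S = 1.0, cif = 0.0;
    int g = 0;
    const int lti = lt[i], owni = own[i] - 1;
    const bool ev = status[i] > 0, evk = status[i] == cause;
    for (int j = 0; j < J; ++j) {
      while (g < G && gidx[g] <= j) { out(i, g) = cif; ++g; }
      const int nj = nr[j] - (j < lti ? 1 : 0);
      if (nj > 0) {
        const int dk = dk_col[j] - (evk && j == owni ? 1 : 0);
        const int da = dt[j] - (ev && j == owni ? 1 : 0);
        cif += S * (double)dk / nj;
        S *= 1.0 - (double)da / nj;
      }
    }
    while (g < G) { out(i, g) = cif; ++g; }
  }
  return out;
}

// Individual cumulative incidence curves from cause-specific discrete hazards.
//
// H    : J x K baseline hazard increments at the distinct event times
// R    : n x K per-subject relative risks exp(x beta_k + z theta_k)
// gidx : per grid time (ascending), #{ut <= t_g}
//
// Builds S(t|x,z) = prod_{j} (1 - sum_k H[j,k] R[i,k]) and
// I_k(t|x,z) = sum_{j} S(t_j - |x,z) H[j,k] R[i,k]; if the total discrete
// hazard at a time exceeds 1 the increments are rescaled to sum to 1
// (curve clipped) and the event is counted in `clipped`.
// Returns list(cif = list of K n x G matrices, surv = n x G, clipped).
// [[Rcpp::export]]
List cif_predict_kernel(NumericMatrix H, NumericMatrix R, IntegerVector gidx) {
  const int J = H.nrow(), K = H.ncol(), n = R.nrow(), G = gidx.size();
  List cifs(K);
  std::vector<NumericMatrix> cm;
  for (int k = 0; k < K; ++k) { NumericMatrix m(n, G); cifs[k] = m; cm.push_back(m); }
  NumericMatrix surv(n, G);
  int clipped = 0;
  if (K == 2) {
    // two competing causes: the common case, kept branch-light
    const double *h1 = &H(0, 0), *h2 = &H(0, 1);
    for (int i = 0; i < n; ++i) {
      const double r1 = R(i, 0), r2 = R(i, 1);
      double S = 1.0, c1 = 0.0, c2 = 0.0;
      int g = 0;
      for (int j = 0; j < J; ++j) {
        while (g < G && gidx[g] <= j) {
          cm[0](i, g) = c1; cm[1](i, g) = c2; surv(i, g) = S; ++g;
        }
        double d1 = h1[j] * r1, d2 = h2[j] * r2, tot = d1 + d2;
        if (tot > 1.0) { d1 /= tot; d2 /= tot; tot = 1.0; ++clipped; }
        c1 += S * d1; c2 += S * d2;
        S *= 1.0 - tot;
      }
      while (g < G) {
        cm[0](i, g) = c1; cm[1](i, g) = c2; surv(i, g) = S; ++g;
      }
    }
  } else {
    std::vector<double> dh(K), cif(K);
    for (int i = 0; i < n; ++i) {
      double S = 1.0;
      std::fill(cif.begin(), cif.end(), 0.0);
      int g = 0;
      for (int j = 0; j < J; ++j) {
        while (g < G && gidx[g] <= j) {
          for (int k = 0; k < K; ++k) cm[k](i, g) = cif[k];
          surv(i, g) = S;
          ++g;
        }
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { dh[k] = H(j, k) * R(i, k); tot += dh[k]; }
        if (tot > 1.0) {
          for (int k = 0; k < K; ++k) dh[k] /= tot;
          tot = 1.0;
          ++clipped;
        }
        for (int k = 0; k < K; ++k) cif[k] += S * dh[k];
        S *= 1.0 - tot;
      }
      while (g < G) {
        for (int k = 0; k < K; ++k) cm[k](i, g) = cif[k];
        surv(i, g) = S;
        ++g;
      }
    }
  }
  return List::create(_["cif"] = cifs, _["surv"] = surv,
                      _["clipped"] = clipped);
}
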