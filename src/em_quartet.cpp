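// Kullback-Leibler projection of a quartet site-pattern distribution onto
// the stochastic general Markov model (optionally an m-category same-tree
// mixture) on the split 12|34, fitted by expectation-maximization.
//
// The latent structure is the two interior nodes u (adjacent to leaves 1,2)
// and v (adjacent to leaves 3,4): parameters are the root distribution pi
// at u, row-stochastic 4x4 matrices M1, M2 (u->leaf1, u->leaf2), N (u->v),
// M3, M4 (v->leaf3, v->leaf4), per category, plus mixture weights.  EM
// keeps every parameter non-negative, so the fitted value measures the
// divergence from the *semi-algebraic* (stochastic) model, not merely from
// the rank variety of the flattening.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline void normalize_rows(double M[4][4]) {
  for (int i = 0; i < 4; ++i) {
    double s = 0;
    for (int j = 0; j < 4; ++j) s += M[i][j];
    if (s <= 0) s = 1;
    for (int j = 0; j < 4; ++j) M[i][j] /= s;
  }
}

struct CatPar {
  double pi[4];
  double M1[4][4], M2[4][4], N[4][4], M3[4][4], M4[4][4];
};

// [[Rcpp::export]]
double em_quartet_kl(NumericVector p, int ncat, int iters, int restarts,
                     double reltol, int pilot_iters = 80) {
  if (p.size() != 256) stop("p must have length 256");
  if (ncat < 1 || ncat > 3) stop("ncat must be 1, 2 or 3");
  // pattern state indices, 0-based: s = 64*x1 + 16*x2 + 4*x3 + x4
  static int X1[256], X2[256], X3[256], X4[256];
  for (int s = 0; s < 256; ++s) {
    X1[s] = (s >> 6) & 3; X2[s] = (s >> 4) & 3;
    X3[s] = (s >> 2) & 3; X4[s] = s & 3;
  }
  double hsat = 0;  // saturated log-likelihood  sum p log p
  for (int s = 0; s < 256; ++s)
    if (p[s] > 0) hsat += p[s] * std::log(p[s]);

  std::vector<CatPar> par(ncat), acc(ncat);
  std::vector<double> w(ncat), wacc(ncat);
  double best = R_NegInf;

  // short-run initialization: every restart gets a pilot phase of `pilot`
  // iterations; only the best pilot is continued to the full budget
  const int pilot = (pilot_iters > 0 && iters > pilot_iters + 40) ? pilot_iters : iters;
  std::vector<CatPar> keep_par(ncat);
  std::vector<double> keep_w(ncat);
  double keep_ll = R_NegInf;

  for (int rs = 0; rs <= restarts; ++rs) {
    int niter;
    if (rs < restarts) {
      niter = pilot;
      // random start: diagonal-leaning stochastic matrices
      for (int c = 0; c < ncat; ++c) {
        double s = 0;
        for (int i = 0; i < 4; ++i) { par[c].pi[i] = R::rgamma(5.0, 1.0); s += par[c].pi[i]; }
        for (int i = 0; i < 4; ++i) par[c].pi[i] /= s;
        double (*mats[5])[4] = { par[c].M1, par[c].M2, par[c].N, par[c].M3, par[c].M4 };
        for (int m = 0; m < 5; ++m) {
          for (int i = 0; i < 4; ++i)
            for (int j = 0; j < 4; ++j)
              mats[m][i][j] = (i == j ? 2.5 : 0.0) + R::rgamma(1.0, 1.0);
          normalize_rows(mats[m]);
        }
        w[c] = 1.0 / ncat;
      }
    } else {
      // final phase: continue the best pilot
      if (iters <= pilot) break;
      niter = iters - pilot;
      par = keep_par;
      w = keep_w;
    }
    double ll = R_NegInf, prev = R_NegInf;
    for (int it = 0; it < niter; ++it) {
      // zero accumulators
      for (int c = 0; c < ncat; ++c) {
        std::memset(&acc[c], 0, sizeof(CatPar));
        wacc[c] = 0;
      }
      ll = 0;
      for (int s = 0; s < 256; ++s) {
        if (p[s] <= 0) continue;
        const int a = X1[s], b = X2[s], cc3 = X3[s], d = X4[s];
        // joint over (cat, u, v) for this pattern
        double J[3][4][4];  // up to 3 categories
        double tot = 0;
        for (int c = 0; c < ncat; ++c) {
          const CatPar &q = par[c];
          for (int u = 0; u < 4; ++u) {
            const double au = q.pi[u] * q.M1[u][a] * q.M2[u][b];
            for (int v = 0; v < 4; ++v) {
              const double t = w[c] * au * q.N[u][v] * q.M3[v][cc3] * q.M4[v][d];
              J[c][u][v] = t;
              tot += t;
            }
          }
        }
        if (tot <= 0) { tot = 1e-300; }
        ll += p[s] * std::log(tot);
        const double scale = p[s] / tot;
        for (int c = 0; c < ncat; ++c) {
          CatPar &A = acc[c];
          for (int u = 0; u < 4; ++u) {
            double ru = 0;
            for (int v = 0; v < 4; ++v) {
              const double r = J[c][u][v] * scale;
              ru += r;
              A.N[u][v] += r;
              A.M3[v][cc3] += r;
              A.M4[v][d] += r;
            }
            A.pi[u] += ru;
            A.M1[u][a] += ru;
            A.M2[u][b] += ru;
            wacc[c] += ru;
          }
        }
      }
      // M-step
      double wsum = 0;
      for (int c = 0; c < ncat; ++c) wsum += wacc[c];
      for (int c = 0; c < ncat; ++c) {
        CatPar &A = acc[c];
        double ps = 0;
        for (int i = 0; i < 4; ++i) ps += A.pi[i];
        if (ps <= 0) ps = 1;
        for (int i = 0; i < 4; ++i) par[c].pi[i] = A.pi[i] / ps;
        double (*src[5])[4] = { A.M1, A.M2, A.N, A.M3, A.M4 };
        double (*dst[5])[4] = { par[c].M1, par[c].M2, par[c].N, par[c].M3, par[c].M4 };
        for (int m = 0; m < 5; ++m) {
          for (int i = 0; i < 4; ++i)
            for (int j = 0; j < 4; ++j)
              dst[m][i][j] = src[m][i][j] + 1e-12;
          normalize_rows(dst[m]);
        }
        w[c] = (wsum > 0) ? wacc[c] / wsum : 1.0 / ncat;
      }
      if (it > 20 && ll - prev < reltol) break;
      prev = ll;
    }
    if (ll > best) best = ll;
    if (rs < restarts && ll > keep_ll) {
      keep_ll = ll;
      keep_par = par;
      keep_w = w;
    }
  }
  double kl = hsat - best;
  return kl > 0 ? kl : 0.0;
}
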