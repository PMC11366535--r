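// Single-site Gibbs sampler for single- and two-trait animal models.
//
// The location system is the mixed-model equations written as a joint
// precision: C = Rinv (x) W'W  +  Ginv (x) Ainv (animal block only), with
// flat priors on fixed effects. Each scalar effect is drawn from its normal
// full conditional in pedigree order; (co)variance components are drawn
// from scaled inverse chi-square (1 trait) or inverse-Wishart (2 traits)
// full conditionals with quadratic-form scale matrices. All randomness
// comes from R's RNG, so chains are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

struct CSC {
  IntegerVector i, p;
  NumericVector x;
  int ncol;
  CSC(const S4& m) {
    i = m.slot("i");
    p = m.slot("p");
    x = m.slot("x");
    IntegerVector dim = m.slot("Dim");
    ncol = dim[1];
  }
};

// diagonal entries of a square dgCMatrix
static NumericVector cscDiag(const CSC& m) {
  NumericVector d(m.ncol);
  for (int j = 0; j < m.ncol; ++j)
    for (int k = m.p[j]; k < m.p[j + 1]; ++k)
      if (m.i[k] == j) { d[j] = m.x[k]; break; }
  return d;
}

// invert a symmetric 1x1 or 2x2 matrix in place-free fashion
static void smallInv(const double* a, double* ai, int nt) {
  if (nt == 1) {
    ai[0] = 1.0 / a[0];
  } else {
    double det = a[0] * a[3] - a[1] * a[2];
    ai[0] = a[3] / det;
    ai[3] = a[0] / det;
    ai[1] = -a[1] / det;
    ai[2] = -a[2] / det;
  }
}

// draw from inverse-Wishart(df, scale) for nt = 1 or 2 via Bartlett
static void riwish(const double* scale, double df, double* out, int nt) {
  if (nt == 1) {
    out[0] = scale[0] / R::rchisq(df);
    return;
  }
  // V = scale^{-1}, lower Cholesky L of V
  double vi[4];
  smallInv(scale, vi, 2);
  double l11 = std::sqrt(vi[0]);
  double l21 = vi[1] / l11;
  double l22 = std::sqrt(vi[3] - l21 * l21);
  // Bartlett factor A (lower triangular)
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = R::norm_rand();
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  // T = L * A, W = T T'
  double t11 = l11 * a11;
  double t21 = l21 * a11 + l22 * a21;
  double t22 = l22 * a22;
  double w11 = t11 * t11;
  double w21 = t21 * t11;
  double w22 = t21 * t21 + t22 * t22;
  double w[4] = {w11, w21, w21, w22};
  smallInv(w, out, 2);
}

// [[Rcpp::export]]
List gibbs_animal_cpp(S4 WtWs, S4 Ainvs, S4 Ws,
                      NumericMatrix y, NumericMatrix Wty,
                      int p, int q, int ntrait,
                      int cycles, int burnin, int thin,
                      double nuA, double nuE,
                      NumericMatrix Sa0, NumericMatrix Se0) {
  CSC WtW(WtWs), Ainv(Ainvs), W(Ws);
  const int M = p + q;
  const int n = y.nrow();
  NumericVector wtwDiag = cscDiag(WtW);
  NumericVector ainvDiag = cscDiag(Ainv);

  NumericMatrix theta(M, ntrait);
  double G[4] = {0, 0, 0, 0}, Rr[4] = {0, 0, 0, 0};
  double Ginv[4], Rinv[4];
  for (int s = 0; s < ntrait; ++s)
    for (int t = 0; t < ntrait; ++t) {
      G[s + 2 * t] = Sa0(s, t);
      Rr[s + 2 * t] = Se0(s, t);
    }

  const int nret = (cycles - burnin) / thin;
  // columns: va(1[,12,2]), ve(1[,12,2]), h2 per trait, [rg, re, rp]
  const int ncols = (ntrait == 1) ? 4 : 11;
  NumericMatrix samples(nret, ncols);
  int kept = 0, jitters = 0;

  std::vector<double> e(n * ntrait), dotW(2), dotA(2);

  for (int cyc = 1; cyc <= cycles; ++cyc) {
    smallInv(G, Ginv, ntrait);
    smallInv(Rr, Rinv, ntrait);

    // ---- location sweep (single site, pedigree order) ----
    for (int i = 0; i < M; ++i) {
      dotW[0] = dotW[1] = dotA[0] = dotA[1] = 0.0;
      for (int k = WtW.p[i]; k < WtW.p[i + 1]; ++k) {
        int j = WtW.i[k];
        double v = WtW.x[k];
        for (int s = 0; s < ntrait; ++s) dotW[s] += v * theta(j, s);
      }
      int ia = i - p;
      if (ia >= 0) {
        for (int k = Ainv.p[ia]; k < Ainv.p[ia + 1]; ++k) {
          int j = Ainv.i[k];
          double v = Ainv.x[k];
          for (int s = 0; s < ntrait; ++s) dotA[s] += v * theta(p + j, s);
        }
      }
      for (int t = 0; t < ntrait; ++t) {
        double diag = Rinv[t + 2 * t] * wtwDiag[i];
        if (ia >= 0) diag += Ginv[t + 2 * t] * ainvDiag[ia];
        double tot = 0.0, rhs = 0.0;
        for (int s = 0; s < ntrait; ++s) {
          tot += Rinv[t + 2 * s] * dotW[s];
          rhs += Rinv[t + 2 * s] * Wty(i, s);
          if (ia >= 0) tot += Ginv[t + 2 * s] * dotA[s];
        }
        double old = theta(i, t);
        double mean = (rhs - tot + diag * old) / diag;
        double draw = mean + R::norm_rand() / std::sqrt(diag);
        theta(i, t) = draw;
        double delta = draw - old;
        dotW[t] += wtwDiag[i] * delta;
        if (ia >= 0) dotA[t] += ainvDiag[ia] * delta;
      }
    }

    // ---- residuals and quadratic forms ----
    for (int t = 0; t < ntrait; ++t)
      for (int r = 0; r < n; ++r) e[r + n * t] = y(r, t);
    for (int j = 0; j < M; ++j)
      for (int k = W.p[j]; k < W.p[j + 1]; ++k) {
        int r = W.i[k];
        double v = W.x[k];
        for (int t = 0; t < ntrait; ++t)
          e[r + n * t] -= v * theta(j, t);
      }
    double Se[4] = {0, 0, 0, 0};
    for (int s = 0; s < ntrait; ++s)
      for (int t = s; t < ntrait; ++t) {
        double acc = 0.0;
        for (int r = 0; r < n; ++r) acc += e[r + n * s] * e[r + n * t];
        Se[s + 2 * t] = Se[t + 2 * s] = acc;
      }

    double Sa[4] = {0, 0, 0, 0};
    {
      std::vector<double> w(q);
      for (int t = 0; t < ntrait; ++t) {
        std::fill(w.begin(), w.end(), 0.0);
        for (int j = 0; j < q; ++j) {
          double aj = theta(p + j, t);
          if (aj == 0.0) continue;
          for (int k = Ainv.p[j]; k < Ainv.p[j + 1]; ++k)
            w[Ainv.i[k]] += Ainv.x[k] * aj;
        }
        for (int s = 0; s <= t; ++s) {
          double acc = 0.0;
          for (int j = 0; j < q; ++j) acc += w[j] * theta(p + j, s);
          Sa[s + 2 * t] = Sa[t + 2 * s] = acc;
        }
      }
    }

    // ---- (co)variance draws ----
    double scaleA[4] = {0, 0, 0, 0}, scaleE[4] = {0, 0, 0, 0};
    for (int s = 0; s < ntrait; ++s)
      for (int t = 0; t < ntrait; ++t) {
        scaleA[s + 2 * t] = Sa[s + 2 * t] + nuA * Sa0(s, t);
        scaleE[s + 2 * t] = Se[s + 2 * t] + nuE * Se0(s, t);
      }
    riwish(scaleA, nuA + q, G, ntrait);
    riwish(scaleE, nuE + n, Rr, ntrait);
    if (ntrait == 2) {
      // guard against numerically singular draws
      for (int tries = 0; tries < 10; ++tries) {
        double det = G[0] * G[3] - G[1] * G[2];
        if (G[0] > 0 && G[3] > 0 && det > 1e-12 * G[0] * G[3]) break;
        ++jitters;
        double tr = G[0] + G[3];
        G[0] += 1e-8 * tr;
        G[3] += 1e-8 * tr;
      }
    }
    bool bad = false;
    for (int k = 0; k < 4; ++k)
      if (!R_finite(G[k]) || !R_finite(Rr[k]) ||
          std::fabs(G[k]) > 1e14 || std::fabs(Rr[k]) > 1e14) bad = true;
    if (bad) stop("divergent variance sample at cycle %d", cyc);

    // ---- record ----
    if (cyc > burnin && (cyc - burnin) % thin == 0) {
      if (ntrait == 1) {
        samples(kept, 0) = G[0];
        samples(kept, 1) = Rr[0];
        samples(kept, 2) = G[0] / (G[0] + Rr[0]);
        samples(kept, 3) = 0.0;
      } else {
        samples(kept, 0) = G[0];
        samples(kept, 1) = G[1];
        samples(kept, 2) = G[3];
        samples(kept, 3) = Rr[0];
        samples(kept, 4) = Rr[1];
        samples(kept, 5) = Rr[3];
        samples(kept, 6) = G[0] / (G[0] + Rr[0]);
        samples(kept, 7) = G[3] / (G[3] + Rr[3]);
        samples(kept, 8) = G[1] / std::sqrt(G[0] * G[3]);
        samples(kept, 9) = Rr[1] / std::sqrt(Rr[0] * Rr[3]);
        double p11 = G[0] + Rr[0], p22 = G[3] + Rr[3];
        samples(kept, 10) = (G[1] + Rr[1]) / std::sqrt(p11 * p22);
      }
      ++kept;
    }
  }

  return List::create(_["samples"] = samples, _["jitters"] = jitters);
}
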