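// Compiled kernels for the particle-smoother EM machinery:
//  - Hill-network ODE right-hand side, vectorized over state rows
//  - fixed-step RK4 propagation of the one-step transition map f
//  - the Q-function transition block (Gaussian one-step residuals) with its
//    analytic gradient w.r.t. theta_sys, obtained by reverse-mode (adjoint)
//    differentiation of the discrete RK4 map — cost independent of the
//    number of parameters
//  - forward-filter backward-simulation (FFBSi) trajectory sampling
//  - stochastic Runge-Kutta (Honeycutt SRKII) integration of the chemical
//    Langevin equation with additive noise of amplitude sqrt(2 D)
// All random draws use R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct NetPar {
  int G, S;
  const int *src, *tgt, *act;          // 0-based source/target, activator flag
  const double *K, *n, *a, *deg, *basal;
};

inline double pospart(double v) { return v > 0.0 ? v : 0.0; }

// Per-row scratch: Hill activities and their local derivatives.
struct RowWork {
  std::vector<double> u, r, dudx, dudK, dudn, drdx, drdK, drdn;
  std::vector<double> actsum, repprod;
  void init(int S, int G) {
    u.assign(S, 0.0); r.assign(S, 1.0);
    dudx.assign(S, 0.0); dudK.assign(S, 0.0); dudn.assign(S, 0.0);
    drdx.assign(S, 0.0); drdK.assign(S, 0.0); drdn.assign(S, 0.0);
    actsum.assign(G, 0.0); repprod.assign(G, 1.0);
  }
};

// g(x) for one state row.  Hill inputs are floored at zero so that small
// negative excursions (allowed by the Gaussian noise model) stay finite.
void rhs_core(const double* x, const NetPar& P, double* gout, RowWork& w, bool deriv) {
  for (int t = 0; t < P.G; ++t) { w.actsum[t] = P.basal[t]; w.repprod[t] = 1.0; }
  for (int s = 0; s < P.S; ++s) {
    const double xc = pospart(x[P.src[s]]);
    const double z = P.K[s] * xc;
    if (P.act[s]) {
      double u = 0.0, dudz = 0.0, dudn = 0.0;
      if (z > 0.0) {
        const double lz = std::log(z);
        u = 1.0 / (1.0 + std::exp(-P.n[s] * lz));   // (Kx)^n / (1 + (Kx)^n)
        const double u1u = u * (1.0 - u);
        dudz = u1u * P.n[s] / z;
        dudn = u1u * lz;
      }
      w.u[s] = u;
      w.actsum[P.tgt[s]] += P.a[s] * u;
      if (deriv) {
        w.dudx[s] = (x[P.src[s]] > 0.0) ? dudz * P.K[s] : 0.0;
        w.dudK[s] = (P.K[s] > 0.0) ? dudz * xc : 0.0;
        w.dudn[s] = dudn;
      }
    } else {
      double r = 1.0, drdz = 0.0, drdn = 0.0;
      if (z > 0.0) {
        const double lz = std::log(z);
        r = 1.0 / (1.0 + std::exp(P.n[s] * lz));    // 1 / (1 + (Kx)^n)
        const double r1r = r * (1.0 - r);
        drdz = -r1r * P.n[s] / z;
        drdn = -r1r * lz;
      }
      w.r[s] = r;
      w.repprod[P.tgt[s]] *= r;
      if (deriv) {
        w.drdx[s] = (x[P.src[s]] > 0.0) ? drdz * P.K[s] : 0.0;
        w.drdK[s] = (P.K[s] > 0.0) ? drdz * xc : 0.0;
        w.drdn[s] = drdn;
      }
    }
  }
  for (int t = 0; t < P.G; ++t)
    gout[t] = w.actsum[t] * w.repprod[t] - P.deg[t] * x[t];
}

// dg/dx (G x G, column-major: J[t + G*s] = d g_t / d x_s), after rhs_core(deriv=TRUE).
void fill_jx(const NetPar& P, const RowWork& w, double* Jx) {
  std::fill(Jx, Jx + P.G * P.G, 0.0);
  for (int t = 0; t < P.G; ++t) Jx[t + P.G * t] -= P.deg[t];
  for (int s = 0; s < P.S; ++s) {
    const int t = P.tgt[s], sc = P.src[s];
    if (P.act[s])
      Jx[t + P.G * sc] += P.a[s] * w.dudx[s] * w.repprod[t];
    else
      Jx[t + P.G * sc] += w.actsum[t] * w.drdx[s] * (w.repprod[t] / w.r[s]);
  }
}

struct ThetaMap {
  // 0-based positions of each parameter inside the flat theta_sys vector;
  // posA[s] = -1 for repressor paths (no amplitude).
  const int *posK, *posN, *posA, *posD, *posB;
  int M;
};

// grad += Jtheta(xs)^T bar_k, evaluated after rhs_core(deriv=TRUE) at xs.
inline void accum_jtheta(const double* xs, const NetPar& P, const RowWork& w,
                         const ThetaMap& tm, const double* bar_k, double* grad) {
  for (int s = 0; s < P.S; ++s) {
    const int t = P.tgt[s];
    const double bk = bar_k[t];
    if (bk == 0.0) continue;
    if (P.act[s]) {
      grad[tm.posK[s]] += P.a[s] * w.dudK[s] * w.repprod[t] * bk;
      grad[tm.posN[s]] += P.a[s] * w.dudn[s] * w.repprod[t] * bk;
      if (tm.posA[s] >= 0) grad[tm.posA[s]] += w.u[s] * w.repprod[t] * bk;
    } else {
      const double rp = w.actsum[t] * (w.repprod[t] / w.r[s]);
      grad[tm.posK[s]] += rp * w.drdK[s] * bk;
      grad[tm.posN[s]] += rp * w.drdn[s] * bk;
    }
  }
  for (int t = 0; t < P.G; ++t) {
    grad[tm.posD[t]] += -xs[t] * bar_k[t];
    grad[tm.posB[t]] += w.repprod[t] * bar_k[t];
  }
}

// Plain RK4 over nsub substeps for one row; if `stages` is non-null, the
// four stage states of every substep are stored there (nsub x 4 x G,
// substep-major) for a subsequent backward pass.
void rk4_row(double* x, const NetPar& P, double dt, int nsub, RowWork& w,
             std::vector<double>& buf, double* stages) {
  const int G = P.G;
  const double h = dt / nsub;
  double* xs = buf.data();
  double* k1 = xs + G; double* k2 = k1 + G; double* k3 = k2 + G; double* k4 = k3 + G;
  for (int it = 0; it < nsub; ++it) {
    double* st = stages ? stages + it * 4 * G : 0;
    if (st) std::copy(x, x + G, st);
    rhs_core(x, P, k1, w, false);
    for (int g = 0; g < G; ++g) xs[g] = x[g] + 0.5 * h * k1[g];
    if (st) std::copy(xs, xs + G, st + G);
    rhs_core(xs, P, k2, w, false);
    for (int g = 0; g < G; ++g) xs[g] = x[g] + 0.5 * h * k2[g];
    if (st) std::copy(xs, xs + G, st + 2 * G);
    rhs_core(xs, P, k3, w, false);
    for (int g = 0; g < G; ++g) xs[g] = x[g] + h * k3[g];
    if (st) std::copy(xs, xs + G, st + 3 * G);
    rhs_core(xs, P, k4, w, false);
    for (int g = 0; g < G; ++g)
      x[g] += h / 6.0 * (k1[g] + 2.0 * k2[g] + 2.0 * k3[g] + k4[g]);
  }
}

// Reverse-mode sweep through the stored RK4 stages of one row: given the
// adjoint lambda = dq/dx_final, accumulates dq/dtheta into grad.  The RK4
// update  x' = x + h/6 (k1 + 2 k2 + 2 k3 + k4)  with
// x2 = x + h/2 k1, x3 = x + h/2 k2, x4 = x + h k3  is differentiated exactly.
void rk4_adjoint(const NetPar& P, const ThetaMap& tm, const double* stages,
                 int nsub, double dt, RowWork& w, std::vector<double>& buf,
                 double* lambda, double* grad) {
  const int G = P.G;
  const double h = dt / nsub;
  double* gdum = buf.data();
  double* Jx = gdum + G;
  double* bark = Jx + G * G;          // 4 stage adjoints, G each
  double* barx = bark + 4 * G;
  for (int it = nsub - 1; it >= 0; --it) {
    const double* st = stages + it * 4 * G;   // x, x2, x3, x4
    for (int g = 0; g < G; ++g) {
      bark[0 * G + g] = h / 6.0 * lambda[g];
      bark[1 * G + g] = h / 3.0 * lambda[g];
      bark[2 * G + g] = h / 3.0 * lambda[g];
      bark[3 * G + g] = h / 6.0 * lambda[g];
      barx[g] = lambda[g];
    }
    // stages in reverse: k4 at x4, k3 at x3, k2 at x2, k1 at x
    for (int stg = 3; stg >= 0; --stg) {
      const double* xs = st + stg * G;
      double* bk = bark + stg * G;
      rhs_core(xs, P, gdum, w, true);
      fill_jx(P, w, Jx);
      accum_jtheta(xs, P, w, tm, bk, grad);
      // bar_xstage = Jx^T bk; propagate into barx and earlier stage adjoints
      for (int s = 0; s < G; ++s) {
        double acc = 0.0;
        for (int t = 0; t < G; ++t) acc += Jx[t + G * s] * bk[t];
        barx[s] += acc;
        if (stg == 3) bark[2 * G + s] += h * acc;          // x4 = x + h k3
        else if (stg == 2) bark[1 * G + s] += 0.5 * h * acc; // x3 = x + h/2 k2
        else if (stg == 1) bark[0 * G + s] += 0.5 * h * acc; // x2 = x + h/2 k1
      }
    }
    for (int g = 0; g < G; ++g) lambda[g] = barx[g];
  }
}

NetPar make_par(int G, const IntegerVector& src, const IntegerVector& tgt,
                const IntegerVector& act, const NumericVector& K,
                const NumericVector& n, const NumericVector& a,
                const NumericVector& deg, const NumericVector& basal) {
  NetPar P;
  P.G = G; P.S = src.size();
  P.src = src.begin(); P.tgt = tgt.begin(); P.act = act.begin();
  P.K = K.begin(); P.n = n.begin(); P.a = a.begin();
  P.deg = deg.begin(); P.basal = basal.begin();
  return P;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix net_rhs_cpp(NumericMatrix X, IntegerVector src, IntegerVector tgt,
                          IntegerVector act, NumericVector K, NumericVector n,
                          NumericVector a, NumericVector deg, NumericVector basal) {
  const int nrow = X.nrow(), G = X.ncol();
  NetPar P = make_par(G, src, tgt, act, K, n, a, deg, basal);
  RowWork w; w.init(P.S, G);
  NumericMatrix out(nrow, G);
  std::vector<double> x(G), g(G);
  for (int i = 0; i < nrow; ++i) {
    for (int c = 0; c < G; ++c) x[c] = X(i, c);
    rhs_core(x.data(), P, g.data(), w, false);
    for (int c = 0; c < G; ++c) out(i, c) = g[c];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix propagate_cpp(NumericMatrix X, IntegerVector src, IntegerVector tgt,
                            IntegerVector act, NumericVector K, NumericVector n,
                            NumericVector a, NumericVector deg, NumericVector basal,
                            double dt, int nsub) {
  const int nrow = X.nrow(), G = X.ncol();
  NetPar P = make_par(G, src, tgt, act, K, n, a, deg, basal);
  RowWork w; w.init(P.S, G);
  NumericMatrix out(nrow, G);
  std::vector<double> x(G), buf(5 * G + 8);
  for (int i = 0; i < nrow; ++i) {
    for (int c = 0; c < G; ++c) x[c] = X(i, c);
    rk4_row(x.data(), P, dt, nsub, w, buf, 0);
    for (int c = 0; c < G; ++c) out(i, c) = x[c];
  }
  return out;
}

// Transition block of the Q function:
//   q = sum_rows beta * sum_i [ -log(2 pi sigma_i^2)/2 - (xnext_i - f_i(xprev))^2 / (2 sigma_i^2) ]
// plus (optionally) its analytic gradient w.r.t. the flat theta_sys vector and
// the weighted squared residual sums per state (used by the sigma update).
// [[Rcpp::export]]
List qtrans_cpp(NumericMatrix Xprev, NumericMatrix Xnext, NumericVector beta,
                IntegerVector src, IntegerVector tgt, IntegerVector act,
                NumericVector K, NumericVector n, NumericVector a,
                NumericVector deg, NumericVector basal,
                double dt, int nsub, NumericVector sigma,
                bool grad, IntegerVector posK, IntegerVector posN, IntegerVector posA,
                IntegerVector posD, IntegerVector posB, int M) {
  const int nrow = Xprev.nrow(), G = Xprev.ncol();
  NetPar P = make_par(G, src, tgt, act, K, n, a, deg, basal);
  RowWork w; w.init(P.S, G);
  ThetaMap tm;
  tm.posK = posK.begin(); tm.posN = posN.begin(); tm.posA = posA.begin();
  tm.posD = posD.begin(); tm.posB = posB.begin(); tm.M = M;

  std::vector<double> sig2inv(G), lognorm(G);
  double lc = 0.0;
  for (int g = 0; g < G; ++g) {
    sig2inv[g] = 1.0 / (sigma[g] * sigma[g]);
    lognorm[g] = -0.5 * std::log(2.0 * M_PI * sigma[g] * sigma[g]);
    lc += lognorm[g];
  }
  std::vector<double> x(G), lambda(G);
  std::vector<double> buf(G + G * G + 5 * G + 8);
  std::vector<double> stages(grad ? nsub * 4 * G : 0);
  std::vector<double> gradv(M, 0.0), resid2(G, 0.0);
  double q = 0.0, betasum = 0.0;
  bool bad = false;
  for (int i = 0; i < nrow; ++i) {
    for (int c = 0; c < G; ++c) x[c] = Xprev(i, c);
    rk4_row(x.data(), P, dt, nsub, w, buf, grad ? stages.data() : 0);
    const double b = beta[i];
    betasum += b;
    for (int c = 0; c < G; ++c) {
      const double r = Xnext(i, c) - x[c];
      if (!std::isfinite(r)) { bad = true; lambda[c] = 0.0; continue; }
      q += b * (-0.5 * r * r * sig2inv[c]);
      resid2[c] += b * r * r;
      lambda[c] = b * r * sig2inv[c];     // dq/df_c for this row
    }
    if (grad && !bad)
      rk4_adjoint(P, tm, stages.data(), nsub, dt, w, buf,
                  lambda.data(), gradv.data());
  }
  q += betasum * lc;
  List out = List::create(_["q"] = bad ? R_NegInf : q,
                          _["resid2"] = NumericVector(resid2.begin(), resid2.end()),
                          _["finite"] = !bad);
  if (grad) out["grad"] = NumericVector(gradv.begin(), gradv.end());
  return out;
}

// Backward-simulation smoother.  xf: filtered particles, dim (T1, P, G);
// logw: normalized log filter weights, (T1 x P); means: f(x_t) for t = 0..T1-2,
// dim (T1-1, P, G); sigma: system-noise sd per state.  Returns ndraw smoothed
// trajectories, dim (T1, ndraw, G).  Uses R's RNG.
// [[Rcpp::export]]
NumericVector ffbsi_cpp(NumericVector xf, NumericMatrix logw, NumericVector means,
                        NumericVector sigma, int ndraw) {
  IntegerVector dims = xf.attr("dim");
  const int T1 = dims[0], Pn = dims[1], G = dims[2];
  const int Tm = T1 - 1;
  NumericVector out(T1 * (R_xlen_t)ndraw * G);
  out.attr("dim") = IntegerVector::create(T1, ndraw, G);
  std::vector<double> lw(Pn), cw(Pn);

  // draw terminal states from the final filter weights
  {
    double mx = R_NegInf;
    for (int i = 0; i < Pn; ++i) mx = std::max(mx, logw(Tm, i));
    double tot = 0.0;
    for (int i = 0; i < Pn; ++i) { cw[i] = (tot += std::exp(logw(Tm, i) - mx)); }
    for (int j = 0; j < ndraw; ++j) {
      const double u = unif_rand() * tot;
      int k = 0; while (k < Pn - 1 && cw[k] < u) ++k;
      for (int g = 0; g < G; ++g)
        out[Tm + T1 * ((R_xlen_t)j + (R_xlen_t)ndraw * g)] =
          xf[Tm + T1 * ((R_xlen_t)k + (R_xlen_t)Pn * g)];
    }
  }
  std::vector<double> s2inv(G);
  for (int g = 0; g < G; ++g) s2inv[g] = 1.0 / (sigma[g] * sigma[g]);

  for (int t = Tm - 1; t >= 0; --t) {
    for (int j = 0; j < ndraw; ++j) {
      double mx = R_NegInf;
      for (int i = 0; i < Pn; ++i) {
        double d2 = 0.0;
        for (int g = 0; g < G; ++g) {
          const double diff = out[(t + 1) + T1 * ((R_xlen_t)j + (R_xlen_t)ndraw * g)]
                            - means[t + Tm * ((R_xlen_t)i + (R_xlen_t)Pn * g)];
          d2 += diff * diff * s2inv[g];
        }
        lw[i] = logw(t, i) - 0.5 * d2;
        if (lw[i] > mx) mx = lw[i];
      }
      double tot = 0.0;
      for (int i = 0; i < Pn; ++i) { cw[i] = (tot += std::exp(lw[i] - mx)); }
      const double u = unif_rand() * tot;
      int k = 0; while (k < Pn - 1 && cw[k] < u) ++k;
      for (int g = 0; g < G; ++g)
        out[t + T1 * ((R_xlen_t)j + (R_xlen_t)ndraw * g)] =
          xf[t + T1 * ((R_xlen_t)k + (R_xlen_t)Pn * g)];
    }
  }
  return out;
}

// Chemical Langevin integration with the Honeycutt SRKII scheme for additive
// noise:  dx/dt = g(x) + xi(t),  <xi_i(t) xi_j(t')> = 2 D delta_ij delta(t-t').
// Per step of size dt the noise increment is sqrt(2 D dt) * psi, psi ~ N(0,1),
// shared between predictor and corrector stages.  States are reflected at 0
// when clip is TRUE (generator-only convention).  Records the state after the
// step counts listed in save_steps (0 = initial state).  Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix srk_sim_cpp(NumericVector x0, IntegerVector src, IntegerVector tgt,
                          IntegerVector act, NumericVector K, NumericVector n,
                          NumericVector a, NumericVector deg, NumericVector basal,
                          double D, double dt, int nsteps, IntegerVector save_steps,
                          bool clip) {
  const int G = x0.size(), nsave = save_steps.size();
  NetPar P = make_par(G, src, tgt, act, K, n, a, deg, basal);
  RowWork w; w.init(P.S, G);
  NumericMatrix out(nsave, G);
  std::vector<double> x(G), F1(G), F2(G), x2(G), psi(G);
  for (int g = 0; g < G; ++g) x[g] = x0[g];
  const double s = std::sqrt(2.0 * D * dt);
  int isave = 0;
  while (isave < nsave && save_steps[isave] == 0) {
    for (int g = 0; g < G; ++g) out(isave, g) = x[g];
    ++isave;
  }
  for (int step = 1; step <= nsteps && isave < nsave; ++step) {
    rhs_core(x.data(), P, F1.data(), w, false);
    for (int g = 0; g < G; ++g) {
      psi[g] = norm_rand();
      x2[g] = x[g] + dt * F1[g] + s * psi[g];
    }
    rhs_core(x2.data(), P, F2.data(), w, false);
    bool bad = false;
    for (int g = 0; g < G; ++g) {
      x[g] += 0.5 * dt * (F1[g] + F2[g]) + s * psi[g];
      if (clip && x[g] < 0.0) x[g] = 0.0;
      if (!std::isfinite(x[g])) bad = true;
    }
    if (bad) stop("Langevin simulation diverged (non-finite state) at step %d", step);
    while (isave < nsave && save_steps[isave] == step) {
      for (int g = 0; g < G; ++g) out(isave, g) = x[g];
      ++isave;
    }
  }
  return out;
}
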