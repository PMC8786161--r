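#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step explicit RK simulation of a network of RCC-controlled Berry
// bienzymatic oscillators.  State layout: m[0..n-1], f[..], p[..], g[..].
// Coupling r_im_i = sum_{k!=i} w_k m_k + eps_i (+ v_i * M when feedback on),
// with M = sum_k m_k recomputed at every RK stage (instantaneous feedback).
// Crank-Nicolson mode replaces the all-to-all sum by a 2x2 grid stencil
// averaging current-stage and previous-step neighbour states (1/2, 1/2).

struct BerryP {
  double gamma, beta, KR, KS, KG, Kdeg, kg, kdeg, ka;
  int hn, hl;
  double KRn, KSl;
};

struct RccP {
  double mu_f, xi_p, xi_g, f_p, f_g;
  bool enabled;
};

// derivative of the full network at one RK stage
static void net_deriv(const std::vector<double>& y, std::vector<double>& dy,
                      int n, const double* w, const double* eps,
                      const double* v, bool feedback, int mode,
                      int rows, int cols, const double* m_prev,
                      const BerryP& bp, const RccP& rc) {
  const double* m = &y[0];
  const double* f = &y[n];
  const double* p = &y[2 * n];
  const double* g = &y[3 * n];
  double S = 0.0, Msum = 0.0;
  for (int k = 0; k < n; ++k) { S += w[k] * m[k]; Msum += m[k]; }
  for (int i = 0; i < n; ++i) {
    double rim;
    if (mode == 0) {
      rim = S - w[i] * m[i] + eps[i];
    } else if (mode == 2) {
      // grid-local finite-difference connections: Moore neighbourhood
      // (8 surrounding cells, periodic wrap), source-indexed weights
      int c = i / rows, r = i % rows;
      double acc = 0.0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (dc == 0 && dr == 0) continue;
          int rr = (r + dr + rows) % rows, cc = (c + dc + cols) % cols;
          int k = cc * rows + rr;
          if (k != i) acc += w[k] * m[k];
        }
      rim = acc + eps[i];
    } else {
      // 2x2 stencil anchored at the unit's grid cell, periodic wrap,
      // column-major unit -> (row, col) mapping
      int c = i / rows, r = i % rows;
      int r1 = (r + 1) % rows, c1 = (c + 1) % cols;
      int idx[4] = { c * rows + r, c * rows + r1, c1 * rows + r, c1 * rows + r1 };
      double acc = 0.0;
      for (int s = 0; s < 4; ++s) {
        int k = idx[s];
        acc += w[k] * 0.5 * (m[k] + m_prev[k]);
      }
      rim = acc + eps[i];
    }
    if (feedback) rim += v[i] * Msum;
    double q = f[i] / (f[i] + rc.mu_f);
    double sp = rc.enabled ? rc.f_p * std::exp(rc.xi_p * q) : rc.f_p;
    double sg = rc.enabled ? rc.f_g * std::exp(rc.xi_g * q) : rc.f_g;
    double flux_gf = bp.kg * f[i] * g[i] / (bp.KG + f[i]);
    double flux_mp = m[i] * p[i] / (1.0 + m[i]);
    double fn = std::pow(f[i], bp.hn);
    double fl = std::pow(f[i], bp.hl);
    dy[i]         = flux_gf - flux_mp + rim;
    dy[n + i]     = -flux_gf + flux_mp - f[i] * p[i] / (1.0 + f[i]);
    dy[2 * n + i] = sp * bp.gamma * fn / (bp.KRn + fn) - bp.ka * p[i] * p[i];
    dy[3 * n + i] = sg * bp.beta * fl / (bp.KSl + fl)
                    - bp.kdeg * g[i] * p[i] / (bp.Kdeg + g[i]);
  }
}

// explicit RK tableaux (fixed step; higher-order solution only)
static void get_tableau(int method, int& ns,
                        std::vector<double>& A, std::vector<double>& b,
                        std::vector<double>& c) {
  if (method == 0) {            // classical RK4
    ns = 4;
    A.assign(16, 0.0); b.assign(4, 0.0); c.assign(4, 0.0);
    A[1 * 4 + 0] = 0.5; A[2 * 4 + 1] = 0.5; A[3 * 4 + 2] = 1.0;
    b[0] = 1.0 / 6; b[1] = 1.0 / 3; b[2] = 1.0 / 3; b[3] = 1.0 / 6;
    c[0] = 0; c[1] = 0.5; c[2] = 0.5; c[3] = 1.0;
  } else if (method == 1) {     // Fehlberg 4(5), 5th-order weights
    ns = 6;
    A.assign(36, 0.0); b.assign(6, 0.0); c.assign(6, 0.0);
    c[0]=0; c[1]=1.0/4; c[2]=3.0/8; c[3]=12.0/13; c[4]=1.0; c[5]=1.0/2;
    A[1*6+0]=1.0/4;
    A[2*6+0]=3.0/32;      A[2*6+1]=9.0/32;
    A[3*6+0]=1932.0/2197; A[3*6+1]=-7200.0/2197; A[3*6+2]=7296.0/2197;
    A[4*6+0]=439.0/216;   A[4*6+1]=-8.0;         A[4*6+2]=3680.0/513;
    A[4*6+3]=-845.0/4104;
    A[5*6+0]=-8.0/27;     A[5*6+1]=2.0;          A[5*6+2]=-3544.0/2565;
    A[5*6+3]=1859.0/4104; A[5*6+4]=-11.0/40;
    b[0]=16.0/135; b[1]=0.0; b[2]=6656.0/12825; b[3]=28561.0/56430;
    b[4]=-9.0/50;  b[5]=2.0/55;
  } else {                      // Dormand-Prince 5(4), 5th-order weights
    ns = 7;
    A.assign(49, 0.0); b.assign(7, 0.0); c.assign(7, 0.0);
    c[0]=0; c[1]=1.0/5; c[2]=3.0/10; c[3]=4.0/5; c[4]=8.0/9; c[5]=1.0; c[6]=1.0;
    A[1*7+0]=1.0/5;
    A[2*7+0]=3.0/40;       A[2*7+1]=9.0/40;
    A[3*7+0]=44.0/45;      A[3*7+1]=-56.0/15;      A[3*7+2]=32.0/9;
    A[4*7+0]=19372.0/6561; A[4*7+1]=-25360.0/2187; A[4*7+2]=64448.0/6561;
    A[4*7+3]=-212.0/729;
    A[5*7+0]=9017.0/3168;  A[5*7+1]=-355.0/33;     A[5*7+2]=46732.0/5247;
    A[5*7+3]=49.0/176;     A[5*7+4]=-5103.0/18656;
    A[6*7+0]=35.0/384;     A[6*7+1]=0.0;           A[6*7+2]=500.0/1113;
    A[6*7+3]=125.0/192;    A[6*7+4]=-2187.0/6784;  A[6*7+5]=11.0/84;
    b[0]=35.0/384; b[1]=0.0; b[2]=500.0/1113; b[3]=125.0/192;
    b[4]=-2187.0/6784; b[5]=11.0/84; b[6]=0.0;
  }
}

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(int n, NumericMatrix w_epochs, NumericMatrix eps_epochs,
                     NumericVector v, bool feedback, int coupling_mode,
                     int grid_rows, int grid_cols,
                     NumericVector bp_in, NumericVector rcc_in,
                     NumericVector state0, double dt, int steps_per_epoch,
                     int record_stride, int method, double ceiling,
                     bool record_units, bool stale_feedback = false) {
  BerryP bp;
  bp.gamma = bp_in[0]; bp.beta = bp_in[1]; bp.KR = bp_in[2]; bp.KS = bp_in[3];
  bp.KG = bp_in[4]; bp.Kdeg = bp_in[5]; bp.kg = bp_in[6]; bp.kdeg = bp_in[7];
  bp.ka = bp_in[8]; bp.hn = (int)bp_in[9]; bp.hl = (int)bp_in[10];
  bp.KRn = std::pow(bp.KR, bp.hn); bp.KSl = std::pow(bp.KS, bp.hl);
  RccP rc;
  rc.mu_f = rcc_in[0]; rc.xi_p = rcc_in[1]; rc.xi_g = rcc_in[2];
  rc.f_p = rcc_in[3]; rc.f_g = rcc_in[4]; rc.enabled = rcc_in[5] != 0.0;

  int n_epochs = eps_epochs.nrow();
  int dim = 4 * n;
  std::vector<double> y(state0.begin(), state0.end());
  std::vector<double> m_prev(n);
  for (int i = 0; i < n; ++i) m_prev[i] = y[i];

  int ns; std::vector<double> A, b, c;
  get_tableau(method, ns, A, b, c);
  std::vector<std::vector<double> > K(ns, std::vector<double>(dim));
  std::vector<double> ytmp(dim), dy(dim);

  long total_steps = (long)n_epochs * steps_per_epoch;
  long n_rec = record_stride > 0 ? total_steps / record_stride : 0;
  NumericVector recM(n_rec), recF(n_rec), rec_t(n_rec);
  IntegerVector rec_epoch(n_rec);
  NumericMatrix rec_m, rec_f;
  if (record_units) { rec_m = NumericMatrix(n_rec, n); rec_f = NumericMatrix(n_rec, n); }

  bool diverged = false;
  long div_step = -1; int div_epoch = -1;
  long step = 0; long irec = 0;
  std::vector<double> w_e(n), eps_e(n), v_eff(n);

  for (int e = 0; e < n_epochs && !diverged; ++e) {
    for (int i = 0; i < n; ++i) { w_e[i] = w_epochs(e, i); eps_e[i] = eps_epochs(e, i); }
    for (int s = 0; s < steps_per_epoch; ++s, ++step) {
      // stale-feedback diagnostic mode: freeze M at the step's start value
      double M0 = 0.0;
      if (stale_feedback) for (int i = 0; i < n; ++i) M0 += y[i];
      for (int st = 0; st < ns; ++st) {
        if (st == 0) {
          ytmp = y;
        } else {
          for (int d = 0; d < dim; ++d) {
            double acc = 0.0;
            for (int j = 0; j < st; ++j) acc += A[st * ns + j] * K[j][d];
            ytmp[d] = y[d] + dt * acc;
          }
        }
        if (stale_feedback && feedback) {
          // use eps + v*M0 folded into eps, disable live feedback
          for (int i = 0; i < n; ++i) eps_e[i] = eps_epochs(e, i) + v[i] * M0;
          net_deriv(ytmp, K[st], n, w_e.data(), eps_e.data(), v_eff.data(),
                    false, coupling_mode, grid_rows, grid_cols, m_prev.data(), bp, rc);
        } else {
          net_deriv(ytmp, K[st], n, w_e.data(), eps_e.data(), v.begin(),
                    feedback, coupling_mode, grid_rows, grid_cols, m_prev.data(), bp, rc);
        }
      }
      if (coupling_mode == 1) for (int i = 0; i < n; ++i) m_prev[i] = y[i];
      bool bad = false;
      for (int d = 0; d < dim; ++d) {
        double acc = 0.0;
        for (int st = 0; st < ns; ++st) acc += b[st] * K[st][d];
        y[d] += dt * acc;
        if (!std::isfinite(y[d]) || std::fabs(y[d]) > ceiling) bad = true;
      }
      if (bad) { diverged = true; div_step = step; div_epoch = e; break; }
      if (record_stride > 0 && (step + 1) % record_stride == 0 && irec < n_rec) {
        double M = 0.0, F = 0.0;
        for (int i = 0; i < n; ++i) { M += y[i]; F += y[n + i]; }
        recM[irec] = M; recF[irec] = F;
        rec_t[irec] = (step + 1) * dt; rec_epoch[irec] = e + 1;
        if (record_units)
          for (int i = 0; i < n; ++i) { rec_m(irec, i) = y[i]; rec_f(irec, i) = y[n + i]; }
        ++irec;
      }
    }
  }
  if (irec < n_rec) {   // truncated by divergence
    recM = head(recM, irec); recF = head(recF, irec);
    rec_t = head(rec_t, irec); rec_epoch = head(rec_epoch, irec);
    if (record_units) {
      rec_m = rec_m(Range(0, std::max<long>(irec - 1, 0)), _);
      rec_f = rec_f(Range(0, std::max<long>(irec - 1, 0)), _);
    }
  }
  List out = List::create(
    _["time"] = rec_t, _["epoch"] = rec_epoch, _["M"] = recM, _["F"] = recF,
    _["state"] = NumericVector(y.begin(), y.end()),
    _["diverged"] = diverged, _["diverge_step"] = (double)div_step,
    _["diverge_epoch"] = div_epoch == -1 ? NA_INTEGER : div_epoch + 1);
  if (record_units) { out["m_units"] = rec_m; out["f_units"] = rec_f; }
  return out;
}
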