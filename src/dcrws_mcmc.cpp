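// Metropolis-within-Gibbs sampler for the two-mode switching
// first-difference correlated random walk with scaled-t Argos errors.
// Single-site random-walk updates for daily states and parameters,
// direct Gibbs draws for the discrete modes; proposal scales adapt
// toward a target acceptance rate during burn-in only.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double th[2], g[2], a[2], sd1, sd2, rho;
  // derived precision terms for the process covariance
  double q11, q22, q12, ldet;
  void refresh() {
    double v1 = sd1 * sd1, v2 = sd2 * sd2, c = rho * sd1 * sd2;
    double det = v1 * v2 - c * c;
    q11 = v2 / det; q22 = v1 / det; q12 = -c / det;
    ldet = std::log(det);
  }
};

struct Data {
  int N;                       // grid days
  std::vector<double> ylon, ylat, frac;
  std::vector<int> node;       // 0-based floor node per fix
  std::vector<double> tlon, tlat, nu, lconst;  // per-fix scales, df, log-constant
  std::vector<std::vector<int>> fixes_at;      // fixes touching each node
  double kappa, sd_prior_scale;
};

inline double t_term(double z, double nu) {
  return -0.5 * (nu + 1.0) * std::log1p(z * z / nu);
}

// full scaled-t log density of fix i given interpolated position (mlon, mlat)
inline double obs_ll_fix(const Data& D, int i, double mlon, double mlat) {
  double zl = (D.ylon[i] - mlon) / D.tlon[i];
  double zb = (D.ylat[i] - mlat) / D.tlat[i];
  return D.lconst[i] + t_term(zl, D.nu[i]) + t_term(zb, D.nu[i]);
}

inline double obs_ll_node(const Data& D, const std::vector<double>& X, int t) {
  double s = 0.0;
  for (int i : D.fixes_at[t]) {
    int k = D.node[i];
    double j = D.frac[i];
    double mlon = (1 - j) * X[2 * k] + j * X[2 * (k + 1)];
    double mlat = (1 - j) * X[2 * k + 1] + j * X[2 * (k + 1) + 1];
    s += obs_ll_fix(D, i, mlon, mlat);
  }
  return s;
}

inline double obs_ll_total(const Data& D, const std::vector<double>& X) {
  double s = 0.0;
  int m = (int)D.ylon.size();
  for (int i = 0; i < m; ++i) {
    int k = D.node[i];
    double j = D.frac[i];
    double mlon = (1 - j) * X[2 * k] + j * X[2 * (k + 1)];
    double mlat = (1 - j) * X[2 * k + 1] + j * X[2 * (k + 1) + 1];
    s += obs_ll_fix(D, i, mlon, mlat);
  }
  return s;
}

inline double bvn_ll(double r1, double r2, const Pars& P) {
  return -M_LN2 - std::log(M_PI) - 0.5 * P.ldet -
    0.5 * (P.q11 * r1 * r1 + 2.0 * P.q12 * r1 * r2 + P.q22 * r2 * r2);
}

// process term for displacement index t (t >= 2, 0-based day index):
// d_t = x_t - x_{t-1} vs gamma_b R(theta_b) d_{t-1}
inline double proc_term(const Data& D, const std::vector<double>& X,
                        const std::vector<int>& B, const Pars& P, int t) {
  double d1 = X[2 * t] - X[2 * (t - 1)];
  double d2 = X[2 * t + 1] - X[2 * (t - 1) + 1];
  double p1 = X[2 * (t - 1)] - X[2 * (t - 2)];
  double p2 = X[2 * (t - 1) + 1] - X[2 * (t - 2) + 1];
  int b = B[t] - 1;
  double c = std::cos(P.th[b]), s = std::sin(P.th[b]);
  double m1 = P.g[b] * (c * p1 - s * p2);
  double m2 = P.g[b] * (s * p1 + c * p2);
  return bvn_ll(d1 - m1, d2 - m2, P);
}

// diffuse first-displacement term: d_1 ~ N(0, kappa * Sigma)
inline double d1_term(const Data& D, const std::vector<double>& X, const Pars& P) {
  double r1 = X[2] - X[0], r2 = X[3] - X[1];
  double k = D.kappa;
  return -M_LN2 - std::log(M_PI) - 0.5 * (P.ldet + 2.0 * std::log(k)) -
    0.5 * (P.q11 * r1 * r1 + 2.0 * P.q12 * r1 * r2 + P.q22 * r2 * r2) / k;
}

inline double proc_ll_total(const Data& D, const std::vector<double>& X,
                            const std::vector<int>& B, const Pars& P) {
  double s = d1_term(D, X, P);
  for (int t = 2; t < D.N; ++t) s += proc_term(D, X, B, P, t);
  return s;
}

// process terms affected by a change in x_t (displacement indices t, t+1, t+2)
inline double local_proc(const Data& D, const std::vector<double>& X,
                         const std::vector<int>& B, const Pars& P, int t) {
  double s = 0.0;
  if (t <= 1) s += d1_term(D, X, P);
  for (int u = std::max(2, t); u <= std::min(D.N - 1, t + 2); ++u)
    s += proc_term(D, X, B, P, u);
  return s;
}

inline double mode_trans_ll(const std::vector<int>& B, const Pars& P, int N) {
  double s = 0.0;
  for (int t = 1; t < N; ++t) {
    double p1 = (B[t - 1] == 1) ? P.a[0] : P.a[1];
    s += std::log(B[t] == 1 ? p1 : 1.0 - p1);
  }
  return s;
}

} // namespace

// [[Rcpp::export]]
List dcrws_chain_cpp(NumericMatrix x_init, IntegerVector b_init,
                     NumericVector pars_init,
                     NumericVector ylon, NumericVector ylat,
                     IntegerVector node, NumericVector frac,
                     NumericVector tau_lon, NumericVector tau_lat,
                     NumericVector nu,
                     int n_iter, int burn_in, int thin,
                     double kappa, double sd_prior_scale, double target_accept,
                     bool fix_modes, bool fix_params) {
  Data D;
  D.N = x_init.nrow();
  int m = ylon.size();
  D.ylon.assign(ylon.begin(), ylon.end());
  D.ylat.assign(ylat.begin(), ylat.end());
  D.frac.assign(frac.begin(), frac.end());
  D.tlon.assign(tau_lon.begin(), tau_lon.end());
  D.tlat.assign(tau_lat.begin(), tau_lat.end());
  D.nu.assign(nu.begin(), nu.end());
  D.kappa = kappa; D.sd_prior_scale = sd_prior_scale;
  D.node.resize(m);
  D.lconst.resize(m);
  D.fixes_at.assign(D.N, {});
  for (int i = 0; i < m; ++i) {
    D.node[i] = node[i] - 1;  // to 0-based
    double v = D.nu[i];
    double c = std::lgamma((v + 1) / 2) - std::lgamma(v / 2) - 0.5 * std::log(v * M_PI);
    D.lconst[i] = 2 * c - std::log(D.tlon[i]) - std::log(D.tlat[i]);
    D.fixes_at[D.node[i]].push_back(i);
    if (D.node[i] + 1 < D.N) D.fixes_at[D.node[i] + 1].push_back(i);
  }

  std::vector<double> X(2 * D.N);
  for (int t = 0; t < D.N; ++t) { X[2 * t] = x_init(t, 0); X[2 * t + 1] = x_init(t, 1); }
  std::vector<int> B(b_init.begin(), b_init.end());

  Pars P;
  P.th[0] = pars_init[0]; P.th[1] = pars_init[1];
  P.g[0] = pars_init[2]; P.g[1] = pars_init[3];
  P.a[0] = pars_init[4]; P.a[1] = pars_init[5];
  P.sd1 = pars_init[6]; P.sd2 = pars_init[7]; P.rho = pars_init[8];
  P.refresh();

  const int n_par = 9;
  std::vector<double> ls_state(D.N, std::log(0.05));   // per-site proposal log-scales
  std::vector<double> ls_par(n_par, std::log(0.1));
  std::vector<int> acc_state(D.N, 0), acc_par(n_par, 0);
  const int batch = 50;

  int S = (n_iter - burn_in) / thin;
  NumericMatrix out_pars(S, n_par);
  NumericVector out_dev(S);
  IntegerMatrix out_modes(S, D.N);
  NumericVector out_states(S * D.N * 2);
  double acc_state_total = 0, prop_state_total = 0;

  RNGScope scope;

  for (int iter = 1; iter <= n_iter; ++iter) {
    bool adapting = iter <= burn_in;

    // --- states: single-site bivariate random-walk Metropolis ---
    for (int t = 0; t < D.N; ++t) {
      double s = std::exp(ls_state[t]);
      double ox = X[2 * t], oy = X[2 * t + 1];
      double cur = obs_ll_node(D, X, t) + local_proc(D, X, B, P, t);
      X[2 * t] = ox + s * norm_rand();
      X[2 * t + 1] = oy + s * norm_rand();
      double prop = obs_ll_node(D, X, t) + local_proc(D, X, B, P, t);
      prop_state_total += 1;
      if (std::log(unif_rand()) < prop - cur) {
        acc_state[t] += 1; acc_state_total += 1;
      } else {
        X[2 * t] = ox; X[2 * t + 1] = oy;
      }
    }

    // --- modes: Gibbs from the full conditional ---
    if (!fix_modes) {
      for (int t = 0; t < D.N; ++t) {
        double lp[2];
        for (int bb = 1; bb <= 2; ++bb) {
          int old = B[t];
          B[t] = bb;
          double v = 0.0;
          if (t >= 2) v += proc_term(D, X, B, P, t);
          if (t >= 1) {
            double p1 = (B[t - 1] == 1) ? P.a[0] : P.a[1];
            v += std::log(bb == 1 ? p1 : 1.0 - p1);
          } else {
            v += std::log(0.5);
          }
          if (t + 1 < D.N) {
            double p1 = (bb == 1) ? P.a[0] : P.a[1];
            v += std::log(B[t + 1] == 1 ? p1 : 1.0 - p1);
          }
          lp[bb - 1] = v;
          B[t] = old;
        }
        double mx = std::max(lp[0], lp[1]);
        double p1 = std::exp(lp[0] - mx);
        double pr = p1 / (p1 + std::exp(lp[1] - mx));
        B[t] = (unif_rand() < pr) ? 1 : 2;
      }
    }

    // --- parameters: scalar random-walk Metropolis ---
    if (!fix_params) {
      for (int p = 0; p < n_par; ++p) {
        double step = std::exp(ls_par[p]) * norm_rand();
        Pars Q = P;
        bool ok = true;
        switch (p) {
          case 0: case 1: {
            double v = Q.th[p] + step;               // wrap onto [-pi, pi)
            Q.th[p] = v - 2 * M_PI * std::floor((v + M_PI) / (2 * M_PI));
            break;
          }
          case 2: Q.g[0] += step; ok = Q.g[0] < 1 && Q.g[0] > Q.g[1]; break;
          case 3: Q.g[1] += step; ok = Q.g[1] > 0 && Q.g[1] < Q.g[0]; break;
          case 4: Q.a[0] += step; ok = Q.a[0] > 0 && Q.a[0] < 1; break;
          case 5: Q.a[1] += step; ok = Q.a[1] > 0 && Q.a[1] < 1; break;
          case 6: Q.sd1 += step; ok = Q.sd1 > 0; break;
          case 7: Q.sd2 += step; ok = Q.sd2 > 0; break;
          case 8: Q.rho += step; ok = Q.rho > -1 && Q.rho < 1; break;
        }
        if (ok) {
          Q.refresh();
          double cur = 0, prop = 0;
          if (p == 0 || p == 1 || p == 2 || p == 3 || p >= 6) {
            cur = proc_ll_total(D, X, B, P);
            prop = proc_ll_total(D, X, B, Q);
          }
          if (p == 4 || p == 5) {
            cur = mode_trans_ll(B, P, D.N);
            prop = mode_trans_ll(B, Q, D.N);
          }
          if (p == 6 || p == 7) {                    // half-normal prior on SDs
            double sc = D.sd_prior_scale;
            cur += -0.5 * (p == 6 ? P.sd1 * P.sd1 : P.sd2 * P.sd2) / (sc * sc);
            prop += -0.5 * (p == 6 ? Q.sd1 * Q.sd1 : Q.sd2 * Q.sd2) / (sc * sc);
          }
          if (std::log(unif_rand()) < prop - cur) { P = Q; acc_par[p] += 1; }
        }
      }
    }

    // --- adapt proposal scales during burn-in ---
    if (adapting && iter % batch == 0) {
      double delta = std::min(0.1, 1.0 / std::sqrt((double)iter / batch));
      for (int t = 0; t < D.N; ++t) {
        ls_state[t] += ((double)acc_state[t] / batch > target_accept) ? delta : -delta;
        acc_state[t] = 0;
      }
      for (int p = 0; p < n_par; ++p) {
        ls_par[p] += ((double)acc_par[p] / batch > target_accept) ? delta : -delta;
        acc_par[p] = 0;
      }
    }

    // --- retain ---
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int s_idx = (iter - burn_in) / thin - 1;
      out_pars(s_idx, 0) = P.th[0]; out_pars(s_idx, 1) = P.th[1];
      out_pars(s_idx, 2) = P.g[0]; out_pars(s_idx, 3) = P.g[1];
      out_pars(s_idx, 4) = P.a[0]; out_pars(s_idx, 5) = P.a[1];
      out_pars(s_idx, 6) = P.sd1; out_pars(s_idx, 7) = P.sd2;
      out_pars(s_idx, 8) = P.rho;
      out_dev[s_idx] = -2.0 * obs_ll_total(D, X);
      for (int t = 0; t < D.N; ++t) {
        out_modes(s_idx, t) = B[t];
        out_states[s_idx + (std::size_t)S * t] = X[2 * t];
        out_states[s_idx + (std::size_t)S * (D.N + t)] = X[2 * t + 1];
      }
    }
  }

  out_states.attr("dim") = IntegerVector::create(S, D.N, 2);
  return List::create(
    _["params"] = out_pars,
    _["deviance"] = out_dev,
    _["modes"] = out_modes,
    _["states"] = out_states,
    _["accept_rate_states"] = prop_state_total > 0 ? acc_state_total / prop_state_total : 0.0);
}
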