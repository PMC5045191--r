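// Inner loops of the Hebbian learning dynamics. Receptive-field learning
// needs ~1e6 sequential weight updates (each renormalized), which is the one
// hot path of the package; everything else stays in R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// A nonlinearity is marshalled from R as a chain of elementary stages
// (see nl_stage_spec() on the R side); evaluation applies them in order.
struct Stage {
  int op;
  double p1, p2;
  std::vector<double> grid_u, grid_f; // tabulated kinds
};

static std::vector<Stage> parse_stages(List stages) {
  std::vector<Stage> out;
  for (R_xlen_t i = 0; i < stages.size(); ++i) {
    List st = stages[i];
    Stage s;
    s.op = as<int>(st["op"]);
    NumericVector par = st["par"];
    s.p1 = par.size() > 0 ? par[0] : 0.0;
    s.p2 = par.size() > 1 ? par[1] : 0.0;
    if (s.op == 14) {
      s.grid_u = as<std::vector<double>>(st["grid_u"]);
      s.grid_f = as<std::vector<double>>(st["grid_f"]);
    }
    out.push_back(s);
  }
  return out;
}

static inline double eval_stage(const Stage& s, double u) {
  switch (s.op) {
    case 0: return u;                                        // linear
    case 1: return u > s.p1 ? u - s.p1 : 0.0;                // linear rectifier
    case 2: {                                                // quadratic rectifier
      double t = u > s.p1 ? u - s.p1 : 0.0;
      return t * (t - s.p2);
    }
    case 3: return 1.0 / (1.0 + std::exp(-2.0 * (u - s.p1))); // sigmoid
    case 4: return -std::tanh(u - s.p1);                      // negative sigmoid
    case 5: return u > 0 ? std::pow(u, s.p1) : 0.0;           // rectified power
    case 6: return u * u * u;                                 // cubic
    case 7: return std::sin(u);
    case 8: return std::cos(u);
    case 9: {                                                 // symmetric rectifier
      double a = std::fabs(u) - s.p1;
      return a > 0 ? a : 0.0;
    }
    case 10: return u > s.p2 ? s.p1 * (u - s.p2) : 0.0;       // f-I: a*(u-theta)+
    case 11: return u * u - s.p1 * u;                         // quadratic plasticity
    case 12: return u < s.p1 ? 0.0 : u;                       // L0 activation
    case 13: return s.p1 * u;                                 // scale (negation)
    case 14: {                                                // tabulated, linear interp
      const std::vector<double>& g = s.grid_u;
      const std::vector<double>& f = s.grid_f;
      if (u <= g.front()) return f.front();
      if (u >= g.back()) return f.back();
      size_t hi = std::upper_bound(g.begin(), g.end(), u) - g.begin();
      double w = (u - g[hi - 1]) / (g[hi] - g[hi - 1]);
      return f[hi - 1] * (1.0 - w) + f[hi] * w;
    }
    case 15: {                                                // cauchy activation
      if (u <= 0) return 0.0;
      double lam = s.p1, lo = 0.0, hi = u;
      for (int it = 0; it < 64; ++it) {
        double mid = 0.5 * (lo + hi);
        double T = mid + 2.0 * lam * mid / (1.0 + mid * mid);
        if (T < u) lo = mid; else hi = mid;
      }
      return 0.5 * (lo + hi);
    }
    default: stop("unknown nonlinearity stage op");
  }
  return 0.0;
}

static inline double eval_chain(const std::vector<Stage>& chain, double u) {
  for (const Stage& s : chain) u = eval_stage(s, u);
  return u;
}

// [[Rcpp::export(name = ".eval_chain_cpp")]]
NumericVector eval_chain_cpp(List stages, NumericVector u) {
  std::vector<Stage> chain = parse_stages(stages);
  NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i) out[i] = eval_chain(chain, u[i]);
  return out;
}

// Sequential single-neuron learning: w <- normalize(w + eta * x * f(w'x)).
// Xt is d x n (samples in columns); `order` is the 1-based presentation
// sequence (concatenated shuffled epochs).
// [[Rcpp::export(name = ".hebb_learn_cpp")]]
List hebb_learn_cpp(NumericMatrix Xt, NumericVector w0, IntegerVector order,
                    NumericVector eta, List stages, int checkpoint_every) {
  const int d = Xt.nrow();
  std::vector<Stage> chain = parse_stages(stages);
  std::vector<double> w(w0.begin(), w0.end());
  const R_xlen_t n_steps = order.size();
  bool per_step_eta = eta.size() == n_steps;
  std::vector<std::vector<double>> checkpoints;

  for (R_xlen_t i = 0; i < n_steps; ++i) {
    const double* x = &Xt(0, order[i] - 1);
    double u = 0.0;
    for (int j = 0; j < d; ++j) u += w[j] * x[j];
    double fu = eval_chain(chain, u);
    if (fu != 0.0) {
      double e = (per_step_eta ? eta[i] : eta[0]) * fu;
      double nrm2 = 0.0;
      for (int j = 0; j < d; ++j) { w[j] += e * x[j]; nrm2 += w[j] * w[j]; }
      double nrm = std::sqrt(nrm2);
      if (!std::isfinite(nrm) || nrm > 1e6 || nrm == 0.0) {
        stop("learning diverged at step %d (eta_w = %g)", (int)(i + 1),
             per_step_eta ? eta[i] : eta[0]);
      }
      for (int j = 0; j < d; ++j) w[j] /= nrm;
    }
    if (checkpoint_every > 0 && (i + 1) % checkpoint_every == 0) {
      checkpoints.push_back(w);
    }
  }

  NumericMatrix cp(checkpoints.size(), d);
  for (size_t r = 0; r < checkpoints.size(); ++r)
    for (int j = 0; j < d; ++j) cp(r, j) = checkpoints[r][j];
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["checkpoints"] = cp,
                      _["n_steps"] = (double)n_steps);
}

// Laterally inhibited network: per sample, recurrent inference by forward
// Euler (y = g(u), tau_u du = -u + W'x - V y), Hebbian feed-forward update
// dw_j = eta_w * x * h(y_j) with column renormalization, anti-Hebbian
// lateral update dv_jk = eta_v * (y_j - <y_j>) y_k clamped at 0 with zero
// diagonal, and an EMA update of <y_j>.
// [[Rcpp::export(name = ".net_learn_cpp")]]
List net_learn_cpp(NumericMatrix Xt, NumericMatrix W0, NumericMatrix V0,
                   NumericVector y_mean0, IntegerVector order,
                   double eta_w, double eta_v, List g_stages, List h_stages,
                   double alpha, int n_iter, double conv_tol, double tau_ema) {
  const int d = Xt.nrow();
  const int K = W0.ncol();
  std::vector<Stage> g = parse_stages(g_stages);
  std::vector<Stage> h = parse_stages(h_stages); // empty chain = identity
  NumericMatrix W = clone(W0);
  NumericMatrix V = clone(V0);
  std::vector<double> y_mean(y_mean0.begin(), y_mean0.end()), b(K), u(K), y(K), du(K);
  const double ema = 1.0 / tau_ema;
  R_xlen_t n_unconverged = 0;

  for (R_xlen_t i = 0; i < order.size(); ++i) {
    const double* x = &Xt(0, order[i] - 1);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) s += W(j, k) * x[j];
      b[k] = s;
    }
    bool lateral = false;
    for (int k = 0; k < K * K; ++k) if (V[k] != 0.0) { lateral = true; break; }
    if (!lateral) {
      for (int k = 0; k < K; ++k) y[k] = eval_chain(g, b[k]);
    } else {
      std::fill(u.begin(), u.end(), 0.0);
      for (int k = 0; k < K; ++k) y[k] = eval_chain(g, 0.0);
      bool converged = false;
      for (int it = 0; it < n_iter; ++it) {
        double maxdu = 0.0;
        for (int k = 0; k < K; ++k) {
          double inh = 0.0;
          for (int l = 0; l < K; ++l) inh += V(k, l) * y[l];
          du[k] = alpha * (-u[k] + b[k] - inh);
        }
        for (int k = 0; k < K; ++k) {
          u[k] += du[k];
          if (!std::isfinite(u[k])) stop("inference dynamics produced non-finite values");
          y[k] = eval_chain(g, u[k]);
          double a = std::fabs(du[k]);
          if (a > maxdu) maxdu = a;
        }
        if (maxdu < conv_tol) { converged = true; break; }
      }
      if (!converged) ++n_unconverged;
    }
    // feed-forward update, multiplicative normalization
    for (int k = 0; k < K; ++k) {
      double hy = h.empty() ? y[k] : eval_chain(h, y[k]);
      if (hy == 0.0) continue;
      double e = eta_w * hy, nrm2 = 0.0;
      for (int j = 0; j < d; ++j) { W(j, k) += e * x[j]; nrm2 += W(j, k) * W(j, k); }
      double nrm = std::sqrt(nrm2);
      if (!std::isfinite(nrm) || nrm > 1e6 || nrm == 0.0) {
        stop("network learning diverged (eta_w = %g)", eta_w);
      }
      for (int j = 0; j < d; ++j) W(j, k) /= nrm;
    }
    // anti-Hebbian lateral update with Dale constraint
    if (eta_v > 0.0 && K > 1) {
      for (int k = 0; k < K; ++k) {
        for (int l = 0; l < K; ++l) {
          if (k == l) continue;
          double v = V(k, l) + eta_v * (y[k] - y_mean[k]) * y[l];
          V(k, l) = v > 0.0 ? v : 0.0;
        }
      }
    }
    for (int k = 0; k < K; ++k) y_mean[k] = (1.0 - ema) * y_mean[k] + ema * y[k];
  }

  return List::create(_["W"] = W, _["V"] = V,
                      _["y_mean"] = NumericVector(y_mean.begin(), y_mean.end()),
                      _["n_unconverged"] = (double)n_unconverged,
                      _["n_steps"] = (double)order.size());
}
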