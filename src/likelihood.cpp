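#include <Rcpp.h>
using namespace Rcpp;

// Full parameter vector layout shared with R/models.R (expand_params):
//   0 lr_pos, 1 lr_neg, 2 ca_pos, 3 ca_neg, 4 decay, 5 prior, 6 m, 7 bias
// update_type: 0 = credit-assignment spreading, 1 = decay-to-prior

static const double PROB_FLOOR = 1e-12;

// One pass over the trial sequence.  Computes per-trial choice
// probabilities of the observed investment under the sigmoid + Gaussian
// density rule and applies the variant's value update.  Missed trials
// contribute no likelihood and trigger no update (values carried through).
static double run_trials(const IntegerVector& stim,
                         const IntegerVector& choice_idx,
                         const NumericVector& reward,
                         const LogicalVector& missed,
                         const NumericVector& options,
                         int n_stim,
                         const NumericVector& par,
                         int update_type,
                         double max_inv,
                         double sigma,
                         bool trace,
                         NumericMatrix& V_out,
                         NumericVector& delta_out,
                         NumericVector& pred_out,
                         NumericVector& pobs_out) {
  const double lr_pos = par[0], lr_neg = par[1];
  const double ca_pos = par[2], ca_neg = par[3];
  const double decay  = par[4], prior  = par[5];
  const double m      = par[6], bias   = par[7];
  const int n_trials = stim.size();
  const int n_opt = options.size();
  const double inv_2s2 = 1.0 / (2.0 * sigma * sigma);

  std::vector<double> V(n_stim, prior);
  if (trace) for (int s = 0; s < n_stim; ++s) V_out(0, s) = prior;

  double nll = 0.0;
  for (int t = 0; t < n_trials; ++t) {
    const int j = stim[t] - 1;
    if (missed[t]) {
      if (trace) {
        for (int s = 0; s < n_stim; ++s) V_out(t + 1, s) = V[s];
        delta_out[t] = NA_REAL; pred_out[t] = NA_REAL; pobs_out[t] = NA_REAL;
      }
      continue;
    }
    // predicted investment from the sigmoid readout of V
    const double z = -m * (V[j] - bias);
    const double pred = max_inv / (1.0 + std::exp(z));
    // Gaussian density over the discrete options, renormalized each trial
    double denom = 0.0, num = 0.0;
    for (int o = 0; o < n_opt; ++o) {
      const double d = options[o] - pred;
      const double w = std::exp(-d * d * inv_2s2);
      denom += w;
      if (o == choice_idx[t] - 1) num = w;
    }
    double p = num / denom;
    if (p < PROB_FLOOR) p = PROB_FLOOR;
    nll -= std::log(p);

    const double delta = reward[t] - V[j];
    const double a  = (delta >= 0.0) ? lr_pos : lr_neg;
    if (update_type == 1) {
      // decay model: full credit to the engaged stimulus, others relax to prior
      for (int s = 0; s < n_stim; ++s)
        if (s != j) V[s] += decay * (prior - V[s]);
      V[j] += a * delta;
    } else {
      const double ca = (delta >= 0.0) ? ca_pos : ca_neg;
      if (n_stim > 1) {
        const double spread = a * delta * (1.0 - ca) / (n_stim - 1);
        for (int s = 0; s < n_stim; ++s)
          if (s != j) V[s] += spread;
      }
      V[j] += a * delta * ca;
    }
    if (trace) {
      for (int s = 0; s < n_stim; ++s) V_out(t + 1, s) = V[s];
      delta_out[t] = delta; pred_out[t] = pred; pobs_out[t] = p;
    }
  }
  return nll;
}

// [[Rcpp::export(name = ".ca_nll_cpp")]]
double ca_nll_cpp(IntegerVector stim, IntegerVector choice_idx,
                  NumericVector reward, LogicalVector missed,
                  NumericVector options, int n_stim,
                  NumericVector par, int update_type,
                  double max_inv, double sigma) {
  NumericMatrix V_dummy(0, 0);
  NumericVector d_dummy(0), p_dummy(0), q_dummy(0);
  return run_trials(stim, choice_idx, reward, missed, options, n_stim,
                    par, update_type, max_inv, sigma, false,
                    V_dummy, d_dummy, p_dummy, q_dummy);
}

// [[Rcpp::export(name = ".ca_trace_cpp")]]
List ca_trace_cpp(IntegerVector stim, IntegerVector choice_idx,
                  NumericVector reward, LogicalVector missed,
                  NumericVector options, int n_stim,
                  NumericVector par, int update_type,
                  double max_inv, double sigma) {
  const int n_trials = stim.size();
  NumericMatrix V(n_trials + 1, n_stim);
  NumericVector delta(n_trials), pred(n_trials), pobs(n_trials);
  double nll = run_trials(stim, choice_idx, reward, missed, options, n_stim,
                          par, update_type, max_inv, sigma, true,
                          V, delta, pred, pobs);
  return List::create(_["nll"] = nll, _["V"] = V, _["delta"] = delta,
                      _["pred"] = pred, _["p_obs"] = pobs);
}

// Objective over a model's free parameters p: the full 8-slot vector is
// base + M p (M and base encode the variant's parameter tying), so the
// optimizer never crosses into R during a line search.
static double nll_free(const NumericVector& p, const NumericMatrix& M,
                       const NumericVector& base,
                       const IntegerVector& stim,
                       const IntegerVector& choice_idx,
                       const NumericVector& reward,
                       const LogicalVector& missed,
                       const NumericVector& options, int n_stim,
                       int update_type, double max_inv, double sigma) {
  NumericVector full(8);
  for (int r = 0; r < 8; ++r) {
    double v = base[r];
    for (int c = 0; c < p.size(); ++c) v += M(r, c) * p[c];
    full[r] = v;
  }
  NumericMatrix V_dummy(0, 0);
  NumericVector d_dummy(0), p_dummy(0), q_dummy(0);
  return run_trials(stim, choice_idx, reward, missed, options, n_stim,
                    full, update_type, max_inv, sigma, false,
                    V_dummy, d_dummy, p_dummy, q_dummy);
}

// [[Rcpp::export(name = ".ca_nll_free_cpp")]]
double ca_nll_free_cpp(NumericVector p, NumericMatrix M, NumericVector base,
                       IntegerVector stim, IntegerVector choice_idx,
                       NumericVector reward, LogicalVector missed,
                       NumericVector options, int n_stim, int update_type,
                       double max_inv, double sigma) {
  return nll_free(p, M, base, stim, choice_idx, reward, missed, options,
                  n_stim, update_type, max_inv, sigma);
}

// Central-difference gradient of the free-parameter objective.
// [[Rcpp::export(name = ".ca_nll_grad_cpp")]]
NumericVector ca_nll_grad_cpp(NumericVector p, NumericMatrix M,
                              NumericVector base, IntegerVector stim,
                              IntegerVector choice_idx, NumericVector reward,
                              LogicalVector missed, NumericVector options,
                              int n_stim, int update_type, double max_inv,
                              double sigma, double eps) {
  const int k = p.size();
  NumericVector g(k), ph(clone(p));
  for (int i = 0; i < k; ++i) {
    const double h = eps * std::max(1.0, std::abs(p[i]));
    ph[i] = p[i] + h;
    const double fp = nll_free(ph, M, base, stim, choice_idx, reward, missed,
                               options, n_stim, update_type, max_inv, sigma);
    ph[i] = p[i] - h;
    const double fm = nll_free(ph, M, base, stim, choice_idx, reward, missed,
                               options, n_stim, update_type, max_inv, sigma);
    ph[i] = p[i];
    g[i] = (fp - fm) / (2.0 * h);
  }
  return g;
}
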