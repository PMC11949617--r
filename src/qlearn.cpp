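#include <Rcpp.h>
using namespace Rcpp;

// Numerically stable log(1 / (1 + exp(-x)))
static inline double log_logistic(double x) {
  if (x > 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// ---------------------------------------------------------------------------
// Per-trial Q-learning log-likelihood for a stacked set of participants.
//
// Trials must be contiguous per participant and in presentation order
// (training before test). Q-values are reset to zero at each participant
// boundary, evolve on training trials (phase == 0) and are frozen on test
// trials (phase == 1). `reward` is ignored for test trials.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_pointwise_loglik(IntegerVector pid, IntegerVector phase,
                                   IntegerVector chosen, IntegerVector other,
                                   IntegerVector reward,
                                   NumericVector alpha_r, NumericVector alpha_l,
                                   NumericVector beta) {
  const int T = pid.size();
  NumericVector out(T);
  double Q[6];
  int cur = -1;
  for (int t = 0; t < T; ++t) {
    const int i = pid[t];
    if (i != cur) {
      for (int s = 0; s < 6; ++s) Q[s] = 0.0;
      cur = i;
    }
    const int ch = chosen[t], ot = other[t];
    out[t] = log_logistic(beta[i] * (Q[ch] - Q[ot]));
    if (phase[t] == 0) {
      const double delta = (double)reward[t] - Q[ch];
      const double a = (delta >= 0.0) ? alpha_r[i] : alpha_l[i];
      Q[ch] += a * delta;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forward simulation of one agent over a schedule (training: feedback drawn
// from each symbol's reward probability and Q updated; test: Q frozen, no
// feedback). Uses R's RNG so results are reproducible under set.seed().
// q0 carries the starting Q-values (zeros for training; end-of-training
// values for a test phase).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_phase(IntegerVector left, IntegerVector right,
                        bool feedback, NumericVector reward_probs,
                        double alpha_r, double alpha_l, double beta,
                        NumericVector q0) {
  const int T = left.size();
  IntegerVector choice(T), reward(T);
  NumericVector q = clone(q0);
  for (int t = 0; t < T; ++t) {
    const int l = left[t], r = right[t];
    const double p_left = 1.0 / (1.0 + std::exp(-beta * (q[l] - q[r])));
    const int ch = (unif_rand() < p_left) ? l : r;
    choice[t] = ch;
    if (feedback) {
      const int rew = (unif_rand() < reward_probs[ch]) ? 1 : 0;
      reward[t] = rew;
      const double delta = (double)rew - q[ch];
      const double a = (delta >= 0.0) ? alpha_r : alpha_l;
      q[ch] += a * delta;
    } else {
      reward[t] = NA_INTEGER;
    }
  }
  return List::create(_["choice"] = choice, _["reward"] = reward,
                      _["q_end"] = q);
}

// ---------------------------------------------------------------------------
// Hierarchical sampler.
//
// Non-centred parameterisation: individual latent z_{ip} ~ N(0, 1),
// natural-scale value = Phi(mu_p + sigma_p * z_{ip}) for learning rates and
// beta_cap * Phi(.) for the inverse temperature. Hyper-priors
// mu_p ~ N(0, 1), sigma_p ~ half-Normal(0, sigma_prior_sd[p]).
//
// Adaptive Metropolis-within-Gibbs: joint random-walk proposal on each
// participant's z block, scalar random walks on mu_p and log(sigma_p), with
// Robbins-Monro scale adaptation during warm-up only. All randomness comes
// from R's RNG.
//
// n_par == 2 -> single learning rate model (alpha, beta);
// n_par == 3 -> dual (alpha_reward, alpha_loss, beta).
// ---------------------------------------------------------------------------

struct GroupData {
  const int *pid, *phase, *chosen, *other, *reward;
  int T, N;
  std::vector<int> start, end; // trial ranges per participant
};

// log-likelihood of one participant's trials
static double subj_loglik(const GroupData &d, int i, double ar, double al,
                          double be) {
  double Q[6] = {0, 0, 0, 0, 0, 0};
  double ll = 0.0;
  for (int t = d.start[i]; t < d.end[i]; ++t) {
    const int ch = d.chosen[t], ot = d.other[t];
    ll += log_logistic(be * (Q[ch] - Q[ot]));
    if (d.phase[t] == 0) {
      const double delta = (double)d.reward[t] - Q[ch];
      Q[ch] += ((delta >= 0.0) ? ar : al) * delta;
    }
  }
  return ll;
}

static inline double nat_value(double mu, double sigma, double z, int p,
                               int n_par, double beta_cap) {
  const double x = R::pnorm(mu + sigma * z, 0.0, 1.0, 1, 0);
  const bool is_beta = (p == n_par - 1);
  return is_beta ? beta_cap * x : x;
}

// [[Rcpp::export]]
List cpp_fit_group(IntegerVector pid, IntegerVector phase,
                   IntegerVector chosen, IntegerVector other,
                   IntegerVector reward, int n_subj, int n_par,
                   int n_warmup, int n_iter, NumericVector sigma_prior_sd,
                   double beta_cap, IntegerVector loo_iters) {
  GroupData d;
  d.pid = INTEGER(pid);
  d.phase = INTEGER(phase);
  d.chosen = INTEGER(chosen);
  d.other = INTEGER(other);
  d.reward = INTEGER(reward);
  d.T = pid.size();
  d.N = n_subj;
  d.start.assign(n_subj, -1);
  d.end.assign(n_subj, -1);
  for (int t = 0; t < d.T; ++t) {
    const int i = d.pid[t];
    if (d.start[i] < 0) d.start[i] = t;
    d.end[i] = t + 1;
  }

  const int P = n_par, N = n_subj;
  std::vector<double> mu(P, 0.0), tau(P, std::log(0.2));
  std::vector<double> z(N * P, 0.0);
  // jitter initial state (chain diversity; deterministic under set.seed)
  for (int p = 0; p < P; ++p) {
    mu[p] = 0.2 * norm_rand();
    tau[p] += 0.2 * norm_rand();
  }
  for (int k = 0; k < N * P; ++k) z[k] = 0.2 * norm_rand();

  // natural-scale parameter cache: theta[i*P + p]
  std::vector<double> theta(N * P), ll(N);
  auto refresh_theta_ll = [&](void) {
    for (int i = 0; i < N; ++i) {
      for (int p = 0; p < P; ++p)
        theta[i * P + p] =
            nat_value(mu[p], std::exp(tau[p]), z[i * P + p], p, P, beta_cap);
      const double be = theta[i * P + (P - 1)];
      const double ar = theta[i * P + 0];
      const double al = (P == 3) ? theta[i * P + 1] : ar;
      ll[i] = subj_loglik(d, i, ar, al, be);
    }
  };
  refresh_theta_ll();

  std::vector<double> s_z(N, 0.4), s_mu(P, 0.15), s_tau(P, 0.3);
  const double target_block = 0.3, target_scalar = 0.44;
  long n_acc_z = 0, n_prop_z = 0, n_acc_h = 0, n_prop_h = 0;

  const int total_iter = n_warmup + n_iter;
  NumericMatrix mu_draws(n_iter, P), sigma_draws(n_iter, P);
  NumericVector theta_draws(n_iter * N * P);
  theta_draws.attr("dim") = IntegerVector::create(n_iter, N, P);
  const int n_loo = loo_iters.size();
  NumericMatrix loo_ll(n_loo > 0 ? n_loo : 1, n_loo > 0 ? d.T : 1);
  int loo_next = 0;

  std::vector<double> z_prop(P), th_prop(N), ll_prop(N);

  for (int it = 1; it <= total_iter; ++it) {
    const bool adapting = (it <= n_warmup);
    const double eta = adapting ? std::pow((double)it, -0.6) : 0.0;

    // --- participant z blocks ----------------------------------------------
    for (int i = 0; i < N; ++i) {
      double lp_diff = 0.0;
      for (int p = 0; p < P; ++p) {
        z_prop[p] = z[i * P + p] + s_z[i] * norm_rand();
        lp_diff += 0.5 * (z[i * P + p] * z[i * P + p] - z_prop[p] * z_prop[p]);
      }
      double th_new[3], ar, al, be;
      for (int p = 0; p < P; ++p)
        th_new[p] = nat_value(mu[p], std::exp(tau[p]), z_prop[p], p, P, beta_cap);
      ar = th_new[0];
      al = (P == 3) ? th_new[1] : ar;
      be = th_new[P - 1];
      const double ll_new = subj_loglik(d, i, ar, al, be);
      const double ldiff = ll_new - ll[i] + lp_diff;
      const double acc = (ldiff >= 0.0) ? 1.0 : std::exp(ldiff);
      ++n_prop_z;
      if (unif_rand() < acc) {
        ++n_acc_z;
        for (int p = 0; p < P; ++p) {
          z[i * P + p] = z_prop[p];
          theta[i * P + p] = th_new[p];
        }
        ll[i] = ll_new;
      }
      if (adapting) s_z[i] *= std::exp(eta * (acc - target_block));
    }

    // --- hyper-parameters ---------------------------------------------------
    for (int p = 0; p < P; ++p) {
      // mu_p
      {
        const double mu_new = mu[p] + s_mu[p] * norm_rand();
        const double sig = std::exp(tau[p]);
        double ll_sum_diff = 0.5 * (mu[p] * mu[p] - mu_new * mu_new);
        for (int i = 0; i < N; ++i) {
          th_prop[i] = nat_value(mu_new, sig, z[i * P + p], p, P, beta_cap);
          double ar = (p == 0) ? th_prop[i] : theta[i * P + 0];
          double al;
          if (P == 3)
            al = (p == 1) ? th_prop[i] : theta[i * P + 1];
          else
            al = ar;
          const double be = (p == P - 1) ? th_prop[i] : theta[i * P + (P - 1)];
          ll_prop[i] = subj_loglik(d, i, ar, al, be);
          ll_sum_diff += ll_prop[i] - ll[i];
        }
        const double acc = (ll_sum_diff >= 0.0) ? 1.0 : std::exp(ll_sum_diff);
        ++n_prop_h;
        if (unif_rand() < acc) {
          ++n_acc_h;
          mu[p] = mu_new;
          for (int i = 0; i < N; ++i) {
            theta[i * P + p] = th_prop[i];
            ll[i] = ll_prop[i];
          }
        }
        if (adapting) s_mu[p] *= std::exp(eta * (acc - target_scalar));
      }
      // tau_p = log sigma_p; prior half-N(0, s0) on sigma plus Jacobian
      {
        const double tau_new = tau[p] + s_tau[p] * norm_rand();
        const double sig_old = std::exp(tau[p]), sig_new = std::exp(tau_new);
        const double s0 = sigma_prior_sd[p];
        double ll_sum_diff =
            0.5 * (sig_old * sig_old - sig_new * sig_new) / (s0 * s0) +
            (tau_new - tau[p]);
        for (int i = 0; i < N; ++i) {
          th_prop[i] = nat_value(mu[p], sig_new, z[i * P + p], p, P, beta_cap);
          double ar = (p == 0) ? th_prop[i] : theta[i * P + 0];
          double al;
          if (P == 3)
            al = (p == 1) ? th_prop[i] : theta[i * P + 1];
          else
            al = ar;
          const double be = (p == P - 1) ? th_prop[i] : theta[i * P + (P - 1)];
          ll_prop[i] = subj_loglik(d, i, ar, al, be);
          ll_sum_diff += ll_prop[i] - ll[i];
        }
        const double acc = (ll_sum_diff >= 0.0) ? 1.0 : std::exp(ll_sum_diff);
        ++n_prop_h;
        if (unif_rand() < acc) {
          ++n_acc_h;
          tau[p] = tau_new;
          for (int i = 0; i < N; ++i) {
            theta[i * P + p] = th_prop[i];
            ll[i] = ll_prop[i];
          }
        }
        if (adapting) s_tau[p] *= std::exp(eta * (acc - target_scalar));
      }
    }

    // --- record -------------------------------------------------------------
    if (it > n_warmup) {
      const int k = it - n_warmup - 1; // 0-based saved index
      for (int p = 0; p < P; ++p) {
        mu_draws(k, p) = mu[p];
        sigma_draws(k, p) = std::exp(tau[p]);
      }
      for (int i = 0; i < N; ++i)
        for (int p = 0; p < P; ++p)
          theta_draws[k + n_iter * (i + N * p)] = theta[i * P + p];
      if (loo_next < n_loo && loo_iters[loo_next] == k + 1) {
        // pointwise log-likelihood at this draw
        for (int i = 0; i < N; ++i) {
          double Q[6] = {0, 0, 0, 0, 0, 0};
          const double ar = theta[i * P + 0];
          const double al = (P == 3) ? theta[i * P + 1] : ar;
          const double be = theta[i * P + (P - 1)];
          for (int t = d.start[i]; t < d.end[i]; ++t) {
            const int ch = d.chosen[t], ot = d.other[t];
            loo_ll(loo_next, t) = log_logistic(be * (Q[ch] - Q[ot]));
            if (d.phase[t] == 0) {
              const double delta = (double)d.reward[t] - Q[ch];
              Q[ch] += ((delta >= 0.0) ? ar : al) * delta;
            }
          }
        }
        ++loo_next;
      }
    }
  }

  return List::create(
      _["mu"] = mu_draws, _["sigma"] = sigma_draws, _["theta"] = theta_draws,
      _["loo_ll"] = (n_loo > 0 ? loo_ll : NumericMatrix(0, 0)),
      _["accept_z"] = (double)n_acc_z / std::max(1L, n_prop_z),
      _["accept_hyper"] = (double)n_acc_h / std::max(1L, n_prop_h));
}
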