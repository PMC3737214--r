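#include <Rcpp.h>
using namespace Rcpp;

// Model codes used across the package: 1 = evl, 2 = pvl_delta, 3 = pvl_decay.
// Parameter order (natural scale):
//   evl:       w, phi, c        (w, phi in (0,1); c in (-5,5))
//   pvl_delta: alpha, lambda, A, c   (A is the delta learning rate)
//   pvl_decay: alpha, lambda, A, c   (A is the decay/recency factor)

static inline double utility_pvl(double x, double alpha, double lambda) {
  if (x >= 0.0) return std::pow(x, alpha);
  return -lambda * std::pow(-x, alpha);
}

// Log-probability of the observed choice under a softmax over theta * E,
// computed with max-subtraction so theta * E up to +/- huge stays finite.
static inline double softmax_logp(const double E[4], double theta, int chosen) {
  double m = theta * E[0];
  for (int j = 1; j < 4; ++j) m = std::max(m, theta * E[j]);
  double s = 0.0;
  for (int j = 0; j < 4; ++j) s += std::exp(theta * E[j] - m);
  return theta * E[chosen] - m - std::log(s);
}

static double session_loglik_core(const int* deck, const double* win,
                                  const double* loss, int horizon,
                                  const double* pars, int model) {
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  double ll = 0.0;
  if (model == 1) {
    const double w = pars[0], phi = pars[1], c = pars[2];
    for (int t = 0; t < horizon; ++t) {
      const double theta = std::pow((t + 1) / 10.0, c);
      const int d = deck[t];
      ll += softmax_logp(E, theta, d);
      const double u = (1.0 - w) * win[t] - w * std::fabs(loss[t]);
      E[d] += phi * (u - E[d]);
    }
  } else {
    const double alpha = pars[0], lambda = pars[1], A = pars[2], c = pars[3];
    const double theta = std::pow(3.0, c) - 1.0;
    for (int t = 0; t < horizon; ++t) {
      const int d = deck[t];
      ll += softmax_logp(E, theta, d);
      const double u = utility_pvl(win[t] + loss[t], alpha, lambda);
      if (model == 3) {
        for (int j = 0; j < 4; ++j) E[j] *= A;
        E[d] += u;
      } else {
        E[d] += A * (u - E[d]);
      }
    }
  }
  return ll;
}

// [[Rcpp::export]]
double session_loglik_cpp(IntegerVector deck, NumericVector win,
                          NumericVector loss, int horizon,
                          NumericVector pars, int model) {
  if (horizon < 0 || horizon > deck.size())
    stop("horizon out of range");
  return session_loglik_core(INTEGER(deck), REAL(win), REAL(loss),
                             horizon, REAL(pars), model);
}

// Per-trial log predictive probabilities (one-step-ahead), same recursion.
// [[Rcpp::export]]
NumericVector session_logp_trials_cpp(IntegerVector deck, NumericVector win,
                                      NumericVector loss, int horizon,
                                      NumericVector pars, int model) {
  NumericVector out(horizon);
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  const double* w = REAL(win);
  const double* l = REAL(loss);
  const int* d = INTEGER(deck);
  if (model == 1) {
    const double wt = pars[0], phi = pars[1], c = pars[2];
    for (int t = 0; t < horizon; ++t) {
      const double theta = std::pow((t + 1) / 10.0, c);
      out[t] = softmax_logp(E, theta, d[t]);
      const double u = (1.0 - wt) * w[t] - wt * std::fabs(l[t]);
      E[d[t]] += phi * (u - E[d[t]]);
    }
  } else {
    const double alpha = pars[0], lambda = pars[1], A = pars[2], c = pars[3];
    const double theta = std::pow(3.0, c) - 1.0;
    for (int t = 0; t < horizon; ++t) {
      out[t] = softmax_logp(E, theta, d[t]);
      const double u = utility_pvl(w[t] + l[t], alpha, lambda);
      if (model == 3) {
        for (int j = 0; j < 4; ++j) E[j] *= A;
        E[d[t]] += u;
      } else {
        E[d[t]] += A * (u - E[d[t]]);
      }
    }
  }
  return out;
}

static inline double to_natural(double z, double lb, double ub) {
  return lb + (ub - lb) * R::pnorm(z, 0.0, 1.0, 1, 0);
}

// lower Cholesky of a small SPD matrix; returns false if not SPD
static bool chol_small(const double* A, double* L, int K) {
  for (int i = 0; i < K * K; ++i) L[i] = 0.0;
  for (int j = 0; j < K; ++j) {
    double d = A[j * K + j];
    for (int k = 0; k < j; ++k) d -= L[j * K + k] * L[j * K + k];
    if (d <= 0.0) return false;
    L[j * K + j] = std::sqrt(d);
    for (int i = j + 1; i < K; ++i) {
      double s = A[i * K + j];
      for (int k = 0; k < j; ++k) s -= L[i * K + k] * L[j * K + k];
      L[i * K + j] = s / L[j * K + j];
    }
  }
  return true;
}

// One MCMC chain for the hierarchical model of one group.
//
// Latent scale: z[i, p] ~ N(mu[p] + beta[p] * age[i], sigma[p]); subject
// parameter p = lb[p] + (ub[p] - lb[p]) * pnorm(z[i, p]). Priors:
// mu[p] ~ N(0, 1), beta[p] ~ N(0, 1), sigma[p] ~ half-normal(1).
// Subjects move by adaptive random-walk Metropolis (joint across params),
// mu/beta by conjugate Gibbs, sigma by adaptive MH on the log scale.
// Uses R's RNG, so a set.seed() before the call fixes the chain.
//
// Returns n_save x (2K [+K] + n*K) matrix: mu (latent), sigma, [beta],
// then subject parameters on the natural scale, subject-major.
// [[Rcpp::export]]
NumericMatrix run_chain_cpp(List decks, List wins, List losses,
                            IntegerVector horizons, int model,
                            NumericVector lb, NumericVector ub,
                            NumericVector age, bool use_age,
                            int n_warmup, int n_save, int n_sweeps,
                            NumericMatrix z_init) {
  const int n = decks.size();
  const int K = lb.size();
  std::vector<const int*> dk(n);
  std::vector<const double*> wn(n), ls(n);
  std::vector<IntegerVector> dk_keep(n);
  std::vector<NumericVector> wn_keep(n), ls_keep(n);
  for (int i = 0; i < n; ++i) {
    dk_keep[i] = as<IntegerVector>(decks[i]);
    wn_keep[i] = as<NumericVector>(wins[i]);
    ls_keep[i] = as<NumericVector>(losses[i]);
    dk[i] = INTEGER(dk_keep[i]);
    wn[i] = REAL(wn_keep[i]);
    ls[i] = REAL(ls_keep[i]);
  }

  std::vector<double> z(n * K), nat(K);
  for (int i = 0; i < n; ++i)
    for (int p = 0; p < K; ++p) z[i * K + p] = z_init(i, p);
  std::vector<double> mu(K, 0.0), beta(K, 0.0), sigma(K, 0.5);
  std::vector<double> lik(n), step(n * K, 0.5), lstep(K, 0.3);
  std::vector<double> gstep(K, 0.2), lik_shift(n);
  std::vector<int> nprop(n * K, 0);
  std::vector<int> sprop(K, 0), gprop(K, 0);
  // adaptive-Metropolis state per subject: running mean / covariance of z
  // (Welford), a Cholesky factor refreshed periodically during warmup,
  // and a scalar scale multiplier
  std::vector<double> am_mean(n * K, 0.0), am_m2(n * K * K, 0.0);
  std::vector<double> am_chol(n * K * K, 0.0), am_scale(n, 1.0);
  std::vector<int> am_cnt(n, 0), am_prop(n, 0);
  std::vector<bool> am_ready(n, false);
  const double am_base = 2.38 * 2.38 / K;
  // the same machinery for a joint shift of (mu, all z) across parameters
  std::vector<double> gm_mean(K, 0.0), gm_m2(K * K, 0.0), gm_chol(K * K, 0.0);
  double gm_scale = 1.0;
  int gm_cnt = 0, gm_prop = 0;
  bool gm_ready = false;

  for (int i = 0; i < n; ++i) {
    for (int p = 0; p < K; ++p) nat[p] = to_natural(z[i * K + p], lb[p], ub[p]);
    lik[i] = session_loglik_core(dk[i], wn[i], ls[i], horizons[i], nat.data(), model);
  }

  const int n_q = 2 * K + (use_age ? K : 0) + n * K;
  NumericMatrix out(n_save, n_q);
  const int n_iter = n_warmup + n_save;

  for (int iter = 0; iter < n_iter; ++iter) {
    // subject-level component-wise random-walk updates; one parameter at
    // a time copes with the alpha-c posterior ridge far better than a
    // joint isotropic proposal
    for (int sweep = 0; sweep < n_sweeps; ++sweep) {
      for (int i = 0; i < n; ++i) {
        for (int p = 0; p < K; ++p) nat[p] = to_natural(z[i * K + p], lb[p], ub[p]);
        for (int p = 0; p < K; ++p) {
          const double zc = z[i * K + p];
          const double zp = zc + step[i * K + p] * norm_rand();
          const double m = mu[p] + (use_age ? beta[p] * age[i] : 0.0);
          const double lp_old = R::dnorm(zc, m, sigma[p], 1);
          const double lp_new = R::dnorm(zp, m, sigma[p], 1);
          const double nat_old = nat[p];
          nat[p] = to_natural(zp, lb[p], ub[p]);
          const double lik_new = session_loglik_core(dk[i], wn[i], ls[i],
                                                     horizons[i], nat.data(), model);
          const bool acc = std::log(unif_rand()) <
            (lik_new + lp_new - lik[i] - lp_old);
          if (acc) {
            z[i * K + p] = zp;
            lik[i] = lik_new;
          } else {
            nat[p] = nat_old;
          }
          if (iter < n_warmup) {
            nprop[i * K + p]++;
            const double gamma = std::min(0.25, 1.0 / std::sqrt((double)nprop[i * K + p]));
            step[i * K + p] *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.44));
          }
        }
      }
    }

    // adaptive-Metropolis bookkeeping and joint proposals: the empirical
    // covariance learned in warmup orients proposals along posterior
    // ridges (notably alpha-c) that axis-aligned moves cross slowly
    if (iter < n_warmup) {
      for (int i = 0; i < n; ++i) {
        am_cnt[i]++;
        const double w = 1.0 / am_cnt[i];
        double dev[8];
        for (int p = 0; p < K; ++p) {
          dev[p] = z[i * K + p] - am_mean[i * K + p];
          am_mean[i * K + p] += w * dev[p];
        }
        for (int p = 0; p < K; ++p)
          for (int q = 0; q < K; ++q)
            am_m2[(i * K + p) * K + q] +=
              dev[p] * (z[i * K + q] - am_mean[i * K + q]);
      }
      if (iter >= 100 && iter % 25 == 0) {
        std::vector<double> cov(K * K);
        for (int i = 0; i < n; ++i) {
          if (am_cnt[i] <= 2 * K) continue;
          for (int p = 0; p < K; ++p)
            for (int q = 0; q < K; ++q)
              cov[p * K + q] = am_m2[(i * K + p) * K + q] / (am_cnt[i] - 1)
                + (p == q ? 1e-6 : 0.0);
          am_ready[i] = chol_small(cov.data(), &am_chol[i * K * K], K);
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!am_ready[i]) continue;
      double eta[8], dz[8];
      for (int p = 0; p < K; ++p) eta[p] = norm_rand();
      // scale mixture: occasional large jumps traverse ridge-shaped and
      // weakly multimodal subject posteriors
      const double mix = unif_rand() < 0.1 ? 3.0 : 1.0;
      const double sc = std::sqrt(am_base) * am_scale[i] * mix;
      double lp_old = 0.0, lp_new = 0.0;
      for (int p = 0; p < K; ++p) {
        dz[p] = 0.0;
        for (int q = 0; q <= p; ++q) dz[p] += am_chol[(i * K + p) * K + q] * eta[q];
        dz[p] *= sc;
        const double m = mu[p] + (use_age ? beta[p] * age[i] : 0.0);
        lp_old += R::dnorm(z[i * K + p], m, sigma[p], 1);
        lp_new += R::dnorm(z[i * K + p] + dz[p], m, sigma[p], 1);
        nat[p] = to_natural(z[i * K + p] + dz[p], lb[p], ub[p]);
      }
      const double lik_new = session_loglik_core(dk[i], wn[i], ls[i],
                                                 horizons[i], nat.data(), model);
      const bool acc = std::log(unif_rand()) <
        (lik_new + lp_new - lik[i] - lp_old);
      if (acc) {
        for (int p = 0; p < K; ++p) z[i * K + p] += dz[p];
        lik[i] = lik_new;
      }
      if (iter < n_warmup) {
        am_prop[i]++;
        const double gamma = std::min(0.25, 1.0 / std::sqrt((double)am_prop[i]));
        am_scale[i] *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.25));
      }
    }

    // group-shift move: translate mu[p] and every subject's z[.,p]
    // jointly; de-couples the hypermean from the subjects when the
    // hyper-SD is small (centered-parameterization funnel)
    for (int p = 0; p < K; ++p) {
      const double delta = gstep[p] * norm_rand();
      double dlik = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int q = 0; q < K; ++q)
          nat[q] = to_natural(z[i * K + q] + (q == p ? delta : 0.0), lb[q], ub[q]);
        lik_shift[i] = session_loglik_core(dk[i], wn[i], ls[i], horizons[i],
                                           nat.data(), model);
        dlik += lik_shift[i] - lik[i];
      }
      const double dprior = R::dnorm(mu[p] + delta, 0.0, 1.0, 1)
        - R::dnorm(mu[p], 0.0, 1.0, 1);
      const bool acc = std::log(unif_rand()) < (dlik + dprior);
      if (acc) {
        mu[p] += delta;
        for (int i = 0; i < n; ++i) {
          z[i * K + p] += delta;
          lik[i] = lik_shift[i];
        }
      }
      if (iter < n_warmup) {
        gprop[p]++;
        const double gamma = std::min(0.25, 1.0 / std::sqrt((double)gprop[p]));
        gstep[p] *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.25));
      }
    }

    // joint correlated shift of the whole group level: delta drawn from
    // the warmup-adapted covariance of mu, applied to mu and every z
    if (iter < n_warmup) {
      gm_cnt++;
      const double w = 1.0 / gm_cnt;
      double dev[8];
      for (int p = 0; p < K; ++p) {
        dev[p] = mu[p] - gm_mean[p];
        gm_mean[p] += w * dev[p];
      }
      for (int p = 0; p < K; ++p)
        for (int q = 0; q < K; ++q)
          gm_m2[p * K + q] += dev[p] * (mu[q] - gm_mean[q]);
      if (iter >= 100 && iter % 25 == 0 && gm_cnt > 2 * K) {
        std::vector<double> cov(K * K);
        for (int p = 0; p < K; ++p)
          for (int q = 0; q < K; ++q)
            cov[p * K + q] = gm_m2[p * K + q] / (gm_cnt - 1)
              + (p == q ? 1e-6 : 0.0);
        gm_ready = chol_small(cov.data(), gm_chol.data(), K);
      }
    }
    if (gm_ready) {
      double eta[8], delta[8];
      for (int p = 0; p < K; ++p) eta[p] = norm_rand();
      const double mix = unif_rand() < 0.1 ? 3.0 : 1.0;
      const double sc = std::sqrt(am_base) * gm_scale * mix;
      double dprior = 0.0;
      for (int p = 0; p < K; ++p) {
        delta[p] = 0.0;
        for (int q = 0; q <= p; ++q) delta[p] += gm_chol[p * K + q] * eta[q];
        delta[p] *= sc;
        dprior += R::dnorm(mu[p] + delta[p], 0.0, 1.0, 1)
          - R::dnorm(mu[p], 0.0, 1.0, 1);
      }
      double dlik = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int p = 0; p < K; ++p)
          nat[p] = to_natural(z[i * K + p] + delta[p], lb[p], ub[p]);
        lik_shift[i] = session_loglik_core(dk[i], wn[i], ls[i], horizons[i],
                                           nat.data(), model);
        dlik += lik_shift[i] - lik[i];
      }
      const bool acc = std::log(unif_rand()) < (dlik + dprior);
      if (acc) {
        for (int p = 0; p < K; ++p) mu[p] += delta[p];
        for (int i = 0; i < n; ++i) {
          for (int p = 0; p < K; ++p) z[i * K + p] += delta[p];
          lik[i] = lik_shift[i];
        }
      }
      if (iter < n_warmup) {
        gm_prop++;
        const double gamma = std::min(0.25, 1.0 / std::sqrt((double)gm_prop));
        gm_scale *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.25));
      }
    }

    // group-level updates
    for (int p = 0; p < K; ++p) {
      const double s2 = sigma[p] * sigma[p];
      if (!use_age) {
        double sz = 0.0;
        for (int i = 0; i < n; ++i) sz += z[i * K + p];
        const double prec = n / s2 + 1.0;
        mu[p] = sz / s2 / prec + norm_rand() / std::sqrt(prec);
      } else {
        // conjugate bivariate normal for (mu, beta)
        double Sa = 0.0, Saa = 0.0, Sz = 0.0, Sza = 0.0;
        for (int i = 0; i < n; ++i) {
          Sa += age[i]; Saa += age[i] * age[i];
          Sz += z[i * K + p]; Sza += z[i * K + p] * age[i];
        }
        const double m11 = n / s2 + 1.0, m12 = Sa / s2, m22 = Saa / s2 + 1.0;
        const double b1 = Sz / s2, b2 = Sza / s2;
        // Cholesky of the 2x2 precision matrix
        const double l11 = std::sqrt(m11);
        const double l21 = m12 / l11;
        const double l22 = std::sqrt(m22 - l21 * l21);
        // mean = M^-1 b via forward/back substitution
        const double y1 = b1 / l11, y2 = (b2 - l21 * y1) / l22;
        const double mean2 = y2 / l22, mean1 = (y1 - l21 * mean2) / l11;
        // draw: mean + L^-T eps
        const double e1 = norm_rand(), e2 = norm_rand();
        const double d2 = e2 / l22, d1 = (e1 - l21 * d2) / l11;
        mu[p] = mean1 + d1;
        beta[p] = mean2 + d2;
      }

      // sigma via MH on log sigma; half-normal(1) prior, log-scale Jacobian
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        const double m = mu[p] + (use_age ? beta[p] * age[i] : 0.0);
        const double r = z[i * K + p] - m;
        ss += r * r;
      }
      const double sig_old = sigma[p];
      const double sig_new = sig_old * std::exp(lstep[p] * norm_rand());
      const double lp_o = -n * std::log(sig_old) - ss / (2.0 * sig_old * sig_old)
        - 0.5 * sig_old * sig_old + std::log(sig_old);
      const double lp_n = -n * std::log(sig_new) - ss / (2.0 * sig_new * sig_new)
        - 0.5 * sig_new * sig_new + std::log(sig_new);
      const bool acc = std::log(unif_rand()) < (lp_n - lp_o);
      if (acc) sigma[p] = sig_new;
      if (iter < n_warmup) {
        sprop[p]++;
        const double gamma = std::min(0.25, 1.0 / std::sqrt((double)sprop[p]));
        lstep[p] *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.44));
      }
    }

    if (iter >= n_warmup) {
      const int r = iter - n_warmup;
      int col = 0;
      for (int p = 0; p < K; ++p) out(r, col++) = mu[p];
      for (int p = 0; p < K; ++p) out(r, col++) = sigma[p];
      if (use_age) for (int p = 0; p < K; ++p) out(r, col++) = beta[p];
      for (int i = 0; i < n; ++i)
        for (int p = 0; p < K; ++p)
          out(r, col++) = to_natural(z[i * K + p], lb[p], ub[p]);
    }
  }
  return out;
}
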