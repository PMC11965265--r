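// Metropolis-within-Gibbs sampler for the multispecies auto-logistic
// dynamic occupancy model with latent-state data augmentation.
//
// Layout conventions (flattened, column-major like R arrays):
//   y[i + I*(j + J*(k + K*t))]   detection data, NA_INTEGER = missing visit
//   X[i + I*(c + C*t)]           scaled occupancy covariates
//   Xd[i + I*(j + J*(c + Cd*t))] scaled detection covariates
//   z[i + I*(k + K*t)]           latent occupancy
//
// All randomness goes through R's RNG (unif_rand / norm_rand) so set.seed()
// on the R side fully determines a chain.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clamp_p(double p) {
  if (p < 1e-12) return 1e-12;
  if (p > 1.0 - 1e-12) return 1.0 - 1e-12;
  return p;
}
static inline double invlogit(double x) {
  return clamp_p(1.0 / (1.0 + std::exp(-x)));
}

struct Sampler {
  // data
  IntegerVector y;
  NumericVector X, Xd;
  int I, J, K, T, C, Cd;
  bool random_effects, autolog, sep_first;
  double mu_prior_sd, fixed_prior_sd, sigma_upper;

  // state
  std::vector<double> b0, b0f, beta /*K*C*/, phi, a0 /*K*T*/, ad /*Cd*/;
  std::vector<int> z, any_det; // I*K*T
  // hyperparameters (random-effects guild only)
  double mu_b0, sg_b0, mu_b0f, sg_b0f, mu_phi, sg_phi;
  std::vector<double> mu_beta, sg_beta, mu_a, sg_a; // C and T

  std::vector<double> curr_ll; // per-species complete-data loglik cache
  // per-cell detection totals and non-missing visit counts (fixed data)
  std::vector<int> det_cnt, vis_cnt;

  inline int yidx(int i, int j, int k, int t) const {
    return i + I * (j + J * (k + K * t));
  }
  inline int zidx(int i, int k, int t) const { return i + I * (k + K * t); }

  double occ_lp(int i, int k, int t) const {
    double lp = (t == 0 && sep_first) ? b0f[k] : b0[k];
    for (int c = 0; c < C; ++c) lp += beta[k + K * c] * X[i + I * (c + C * t)];
    if (t > 0 && autolog) lp += phi[k] * z[zidx(i, k, t - 1)];
    return lp;
  }
  double det_p(int i, int j, int k, int t) const {
    double lp = a0[k + K * t];
    for (int c = 0; c < Cd; ++c)
      lp += ad[c] * Xd[i + I * (j + J * (c + Cd * t))];
    return invlogit(lp);
  }

  // complete-data loglik for species k at the current state
  double sp_loglik(int k) const {
    double ll = 0.0;
    for (int t = 0; t < T; ++t) {
      if (Cd == 0) {
        // p constant over sites and visits: tally detections at occupied
        // cells and use Binomial-style closed sums
        double p = invlogit(a0[k + K * t]);
        long Dn = 0, Vn = 0;
        for (int i = 0; i < I; ++i) {
          double psi = invlogit(occ_lp(i, k, t));
          int id = zidx(i, k, t);
          if (z[id]) {
            ll += std::log(psi);
            Dn += det_cnt[id];
            Vn += vis_cnt[id];
          } else {
            ll += std::log1p(-psi);
          }
        }
        ll += Dn * std::log(p) + (Vn - Dn) * std::log1p(-p);
      } else {
        for (int i = 0; i < I; ++i) {
          double psi = invlogit(occ_lp(i, k, t));
          int zz = z[zidx(i, k, t)];
          ll += zz ? std::log(psi) : std::log1p(-psi);
          if (zz) {
            for (int j = 0; j < J; ++j) {
              int yv = y[yidx(i, j, k, t)];
              if (yv == NA_INTEGER) continue;
              double p = det_p(i, j, k, t);
              ll += yv ? std::log(p) : std::log1p(-p);
            }
          }
          // z = 0: all non-missing y are 0 by construction, mass 1
        }
      }
    }
    return ll;
  }

  double total_loglik() const {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += sp_loglik(k);
    return s;
  }

  // Gibbs draw of every latent cell without a detection, from its full
  // conditional: prior psi, all-zero detection history, and (for t < T-1)
  // the auto-logistic term for year t+1.
  void update_z() {
    for (int t = 0; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        for (int i = 0; i < I; ++i) {
          int id = zidx(i, k, t);
          if (any_det[id]) { z[id] = 1; continue; }
          double psi = invlogit(occ_lp(i, k, t));
          double a = psi, b = 1.0 - psi;
          if (Cd == 0) {
            a *= std::pow(1.0 - invlogit(a0[k + K * t]), vis_cnt[id]);
          } else {
            for (int j = 0; j < J; ++j) {
              int yv = y[yidx(i, j, k, t)];
              if (yv == NA_INTEGER) continue;
              a *= 1.0 - det_p(i, j, k, t); // y must be 0 here
            }
          }
          if (t + 1 < T && autolog) {
            double lp = b0[k];
            for (int c = 0; c < C; ++c)
              lp += beta[k + K * c] * X[i + I * (c + C * (t + 1))];
            double psi1 = invlogit(lp + phi[k]);
            double psi0 = invlogit(lp);
            int zn = z[zidx(i, k, t + 1)];
            a *= zn ? psi1 : (1.0 - psi1);
            b *= zn ? psi0 : (1.0 - psi0);
          }
          z[id] = (unif_rand() < a / (a + b)) ? 1 : 0;
        }
      }
    }
  }
};

static inline double dnorm_log(double x, double m, double s) {
  double r = (x - m) / s;
  return -0.5 * r * r - std::log(s) - 0.9189385332046727;
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(IntegerVector y, NumericVector X, NumericVector Xd,
                   IntegerVector dims, // I, J, K, T, C, Cd
                   bool random_effects, bool autolog, bool sep_first,
                   int n_iter, int n_burnin, int thin,
                   double mu_prior_sd, double fixed_prior_sd,
                   double sigma_upper, double init_scale,
                   bool adapt, int adapt_interval, double target_accept,
                   bool save_z) {
  Sampler S;
  S.y = y; S.X = X; S.Xd = Xd;
  S.I = dims[0]; S.J = dims[1]; S.K = dims[2]; S.T = dims[3];
  S.C = dims[4]; S.Cd = dims[5];
  S.random_effects = random_effects; S.autolog = autolog;
  S.sep_first = sep_first;
  S.mu_prior_sd = mu_prior_sd; S.fixed_prior_sd = fixed_prior_sd;
  S.sigma_upper = sigma_upper;
  const int I = S.I, J = S.J, K = S.K, T = S.T, C = S.C, Cd = S.Cd;

  S.b0.assign(K, 0.0); S.b0f.assign(K, 0.0); S.beta.assign(K * C, 0.0);
  S.phi.assign(K, 0.0); S.a0.assign(K * T, 0.0); S.ad.assign(Cd, 0.0);
  S.mu_b0 = 0; S.sg_b0 = 1; S.mu_b0f = 0; S.sg_b0f = 1;
  S.mu_phi = 0; S.sg_phi = 1;
  S.mu_beta.assign(C, 0.0); S.sg_beta.assign(C, 1.0);
  S.mu_a.assign(T, 0.0); S.sg_a.assign(T, 1.0);

  // latent init: maximal (z = 1 everywhere) so no -Inf start
  S.z.assign(I * K * T, 1);
  S.any_det.assign(I * K * T, 0);
  S.det_cnt.assign(I * K * T, 0);
  S.vis_cnt.assign(I * K * T, 0);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < I; ++i) {
        int id = S.zidx(i, k, t);
        for (int j = 0; j < J; ++j) {
          int yv = y[S.yidx(i, j, k, t)];
          if (yv == NA_INTEGER) continue;
          S.vis_cnt[id]++;
          if (yv == 1) { S.det_cnt[id]++; S.any_det[id] = 1; }
        }
      }

  // species-level scalar blocks: index them for scales/acceptance tracking
  // per species: b0, [b0f], C betas, [phi], T alpha0  -> n_sp_par scalars
  int n_sp_par = 1 + (sep_first ? 1 : 0) + C + (autolog ? 1 : 0) + T;
  int n_scalar = K * n_sp_par + Cd;
  // hyper sigma blocks: b0, [b0f], C, [phi], T families
  int n_fam = random_effects ? (1 + (sep_first ? 1 : 0) + C + (autolog ? 1 : 0) + T) : 0;
  std::vector<double> lscale(n_scalar + n_fam, std::log(init_scale));
  std::vector<int> acc(n_scalar + n_fam, 0), att(n_scalar + n_fam, 0);
  std::vector<int> acc_tot(n_scalar + n_fam, 0), att_tot(n_scalar + n_fam, 0);

  int n_save = (n_iter - n_burnin + thin - 1) / thin;
  // saved parameter columns: species params, alpha_det, hyperparams
  int n_hyp = random_effects ? 2 * n_fam : 0;
  int n_par = K * n_sp_par + Cd + n_hyp;
  NumericMatrix draws(n_save, n_par);
  NumericVector dev(n_save);
  IntegerMatrix zdraws(save_z ? n_save : 0, save_z ? I * K * T : 0);
  IntegerVector zsum(I * K * T);

  S.curr_ll.assign(K, 0.0);
  int cur_iter = 0; // post-burn-in acceptance is tracked separately

  // generic scalar Metropolis step on a species parameter
  auto mh_scalar = [&](double *theta, double pm, double ps, int k, int sidx) {
    double old = *theta;
    double prop = old + std::exp(lscale[sidx]) * norm_rand();
    *theta = prop;
    double new_ll = S.sp_loglik(k);
    double lr = new_ll - S.curr_ll[k] + dnorm_log(prop, pm, ps) -
                dnorm_log(old, pm, ps);
    att[sidx]++;
    if (cur_iter >= n_burnin) att_tot[sidx]++;
    if (std::log(unif_rand()) < lr) {
      S.curr_ll[k] = new_ll; acc[sidx]++;
      if (cur_iter >= n_burnin) acc_tot[sidx]++;
    } else {
      *theta = old;
    }
  };

  // conjugate draw for a community mean given species values and sigma
  auto draw_mu = [&](const double *v, int stride, int n, double sg) {
    double s = 0.0;
    for (int k = 0; k < n; ++k) s += v[k * stride];
    double prec = n / (sg * sg) + 1.0 / (mu_prior_sd * mu_prior_sd);
    double mean = (s / (sg * sg)) / prec;
    return mean + norm_rand() / std::sqrt(prec);
  };
  // log-scale random-walk Metropolis for a community sd, Uniform(0, upper)
  auto update_sigma = [&](const double *v, int stride, int n, double mu,
                          double *sg, int sidx) {
    double old = *sg;
    double prop = old * std::exp(std::exp(lscale[sidx]) * norm_rand());
    att[sidx]++;
    if (cur_iter >= n_burnin) att_tot[sidx]++;
    if (prop <= 0 || prop >= sigma_upper) return;
    double lr = std::log(prop) - std::log(old); // Jacobian of log transform
    for (int k = 0; k < n; ++k) {
      lr += dnorm_log(v[k * stride], mu, prop) - dnorm_log(v[k * stride], mu, old);
    }
    if (std::log(unif_rand()) < lr) {
      *sg = prop; acc[sidx]++;
      if (cur_iter >= n_burnin) acc_tot[sidx]++;
    }
  };

  for (int iter = 0; iter < n_iter; ++iter) {
    cur_iter = iter;
    S.update_z();
    for (int k = 0; k < K; ++k) S.curr_ll[k] = S.sp_loglik(k);

    // species-level effects
    for (int k = 0; k < K; ++k) {
      int base = k * n_sp_par, s = base;
      if (random_effects) {
        mh_scalar(&S.b0[k], S.mu_b0, S.sg_b0, k, s++);
        if (sep_first) mh_scalar(&S.b0f[k], S.mu_b0f, S.sg_b0f, k, s++);
        for (int c = 0; c < C; ++c)
          mh_scalar(&S.beta[k + K * c], S.mu_beta[c], S.sg_beta[c], k, s++);
        if (autolog) mh_scalar(&S.phi[k], S.mu_phi, S.sg_phi, k, s++);
        for (int t = 0; t < T; ++t)
          mh_scalar(&S.a0[k + K * t], S.mu_a[t], S.sg_a[t], k, s++);
      } else {
        mh_scalar(&S.b0[k], 0.0, fixed_prior_sd, k, s++);
        if (sep_first) mh_scalar(&S.b0f[k], 0.0, fixed_prior_sd, k, s++);
        for (int c = 0; c < C; ++c)
          mh_scalar(&S.beta[k + K * c], 0.0, fixed_prior_sd, k, s++);
        if (autolog) mh_scalar(&S.phi[k], 0.0, fixed_prior_sd, k, s++);
        for (int t = 0; t < T; ++t)
          mh_scalar(&S.a0[k + K * t], 0.0, fixed_prior_sd, k, s++);
      }
    }

    // shared detection-covariate effects (full-data Metropolis)
    for (int c = 0; c < Cd; ++c) {
      int sidx = K * n_sp_par + c;
      double old = S.ad[c];
      double tot_old = 0.0;
      for (int k = 0; k < K; ++k) tot_old += S.curr_ll[k];
      S.ad[c] = old + std::exp(lscale[sidx]) * norm_rand();
      std::vector<double> new_ll(K);
      double tot_new = 0.0;
      for (int k = 0; k < K; ++k) { new_ll[k] = S.sp_loglik(k); tot_new += new_ll[k]; }
      double lr = tot_new - tot_old +
                  dnorm_log(S.ad[c], 0.0, fixed_prior_sd) -
                  dnorm_log(old, 0.0, fixed_prior_sd);
      att[sidx]++;
      if (iter >= n_burnin) att_tot[sidx]++;
      if (std::log(unif_rand()) < lr) {
        S.curr_ll = new_ll; acc[sidx]++;
        if (iter >= n_burnin) acc_tot[sidx]++;
      } else {
        S.ad[c] = old;
      }
    }

    // community hyperparameters
    if (random_effects) {
      int f = n_scalar;
      S.mu_b0 = draw_mu(&S.b0[0], 1, K, S.sg_b0);
      update_sigma(&S.b0[0], 1, K, S.mu_b0, &S.sg_b0, f++);
      if (sep_first) {
        S.mu_b0f = draw_mu(&S.b0f[0], 1, K, S.sg_b0f);
        update_sigma(&S.b0f[0], 1, K, S.mu_b0f, &S.sg_b0f, f++);
      }
      for (int c = 0; c < C; ++c) {
        S.mu_beta[c] = draw_mu(&S.beta[K * c], 1, K, S.sg_beta[c]);
        update_sigma(&S.beta[K * c], 1, K, S.mu_beta[c], &S.sg_beta[c], f++);
      }
      if (autolog) {
        S.mu_phi = draw_mu(&S.phi[0], 1, K, S.sg_phi);
        update_sigma(&S.phi[0], 1, K, S.mu_phi, &S.sg_phi, f++);
      }
      for (int t = 0; t < T; ++t) {
        S.mu_a[t] = draw_mu(&S.a0[K * t], 1, K, S.sg_a[t]);
        update_sigma(&S.a0[K * t], 1, K, S.mu_a[t], &S.sg_a[t], f++);
      }
    }

    // proposal adaptation, burn-in only (frozen afterward so the saved
    // portion of the chain is a valid time-homogeneous Markov chain)
    if (adapt && iter < n_burnin && (iter + 1) % adapt_interval == 0) {
      double delta = std::min(0.25, 2.0 / std::sqrt((iter + 1.0) / adapt_interval));
      for (size_t s = 0; s < lscale.size(); ++s) {
        if (att[s] == 0) continue;
        double rate = (double)acc[s] / att[s];
        if (rate > target_accept + 0.05) lscale[s] += delta;
        else if (rate < target_accept - 0.05) lscale[s] -= delta;
        acc[s] = 0; att[s] = 0;
      }
    }

    // save
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0) {
      int srow = (iter - n_burnin) / thin;
      int col = 0;
      for (int k = 0; k < K; ++k) {
        draws(srow, col++) = S.b0[k];
        if (sep_first) draws(srow, col++) = S.b0f[k];
        for (int c = 0; c < C; ++c) draws(srow, col++) = S.beta[k + K * c];
        if (autolog) draws(srow, col++) = S.phi[k];
        for (int t = 0; t < T; ++t) draws(srow, col++) = S.a0[k + K * t];
      }
      for (int c = 0; c < Cd; ++c) draws(srow, col++) = S.ad[c];
      if (random_effects) {
        draws(srow, col++) = S.mu_b0; draws(srow, col++) = S.sg_b0;
        if (sep_first) { draws(srow, col++) = S.mu_b0f; draws(srow, col++) = S.sg_b0f; }
        for (int c = 0; c < C; ++c) {
          draws(srow, col++) = S.mu_beta[c]; draws(srow, col++) = S.sg_beta[c];
        }
        if (autolog) { draws(srow, col++) = S.mu_phi; draws(srow, col++) = S.sg_phi; }
        for (int t = 0; t < T; ++t) {
          draws(srow, col++) = S.mu_a[t]; draws(srow, col++) = S.sg_a[t];
        }
      }
      // conditional (on z) observation-level deviance
      double d = 0.0;
      for (int t = 0; t < T; ++t)
        for (int k = 0; k < K; ++k) {
          if (Cd == 0) {
            double p = invlogit(S.a0[k + K * t]);
            long Dn = 0, Vn = 0;
            for (int i = 0; i < I; ++i) {
              int id = S.zidx(i, k, t);
              if (S.z[id]) { Dn += S.det_cnt[id]; Vn += S.vis_cnt[id]; }
            }
            d += Dn * std::log(p) + (Vn - Dn) * std::log1p(-p);
          } else {
            for (int i = 0; i < I; ++i) {
              if (!S.z[S.zidx(i, k, t)]) continue;
              for (int j = 0; j < J; ++j) {
                int yv = y[S.yidx(i, j, k, t)];
                if (yv == NA_INTEGER) continue;
                double p = S.det_p(i, j, k, t);
                d += yv ? std::log(p) : std::log1p(-p);
              }
            }
          }
        }
      dev[srow] = -2.0 * d;
      for (int c = 0; c < I * K * T; ++c) {
        zsum[c] += S.z[c];
        if (save_z) zdraws(srow, c) = S.z[c];
      }
    }
  }

  NumericVector acc_rate(acc_tot.size());
  for (size_t s = 0; s < acc_tot.size(); ++s)
    acc_rate[s] = att_tot[s] ? (double)acc_tot[s] / att_tot[s] : NA_REAL;
  NumericVector scales(lscale.size());
  for (size_t s = 0; s < lscale.size(); ++s) scales[s] = std::exp(lscale[s]);

  return List::create(
    _["draws"] = draws, _["deviance"] = dev, _["z"] = zdraws,
    _["z_sum"] = zsum, _["accept"] = acc_rate, _["scales"] = scales,
    _["n_save"] = n_save);
}
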