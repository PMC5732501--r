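#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the BYM Poisson log-linear model
//
//   y_i ~ Po(E_i * exp(eta_i)),  eta_i = alpha + beta x_i + gamma_i + eps_i
//
// gamma has the intrinsic CAR prior with symmetric weights W:
//   gamma_i | rest ~ N( sum_j w_ij gamma_j / w_i+ , sigma2_gamma / w_i+ )
// identified by recentring gamma to sum to zero after every sweep (alpha
// absorbs the removed mean). eps_i ~ N(0, sigma_eps^2);
// alpha, beta ~ N(0, prior_var); sigma_eps ~ half-N(0, se_scale2);
// sigma2_gamma ~ Gamma(sg_shape, sg_rate) on the variance, updated by
// random-walk MH on the log scale against its exact full conditional
// (including the (N_eff - n_comp)/2 normalising exponent of the
// constrained ICAR density). Proposal scales adapt during burn-in only.
//
// W is passed in compressed row form: for area i the neighbours are
// W_idx[W_ptr[i] .. W_ptr[i+1]-1] (0-based) with weights W_wt[...].
// Areas with a zero row sum (islands) keep gamma_i = 0.
//
// With use_likelihood = false the Poisson terms are dropped everywhere,
// so the chain targets the joint prior: used for prior-recovery checks.

static inline void adapt_scale(double &sd, int &acc, int &att, double target) {
  if (att >= 100) {
    double rate = (double)acc / att;
    sd *= std::exp(std::max(-0.5, std::min(0.5, rate - target)));
    if (sd < 1e-6) sd = 1e-6;
    if (sd > 50.0) sd = 50.0;
    acc = 0; att = 0;
  }
}

// [[Rcpp::export]]
List bym_mcmc_cpp(IntegerVector y, NumericVector E, NumericVector x,
                  IntegerVector W_ptr, IntegerVector W_idx, NumericVector W_wt,
                  NumericVector W_rowsum,
                  int n_burn, int n_iter, int thin,
                  double prior_var_alpha, double prior_var_beta,
                  double sg_shape, double sg_rate, double se_scale2,
                  bool structured, bool use_likelihood, int n_comp,
                  double alpha0, double beta0,
                  NumericVector gamma0, NumericVector eps0,
                  double sigma2_gamma0, double sigma_eps0) {
  const int N = y.size();
  const int M = n_iter / thin;
  double alpha = alpha0, beta = beta0;
  NumericVector gam = clone(gamma0), eps = clone(eps0);
  double s2g = sigma2_gamma0, se = sigma_eps0;

  // islands and effective dimension of the ICAR density
  std::vector<bool> island(N, false);
  int n_live = 0;
  for (int i = 0; i < N; ++i) {
    island[i] = structured && W_rowsum[i] <= 0.0;
    if (!island[i]) ++n_live;
    if (island[i]) gam[i] = 0.0;
  }
  const double icar_exponent = structured ? 0.5 * (n_live - n_comp) : 0.0;

  double sum_y = 0.0, sum_xy = 0.0;
  for (int i = 0; i < N; ++i) { sum_y += y[i]; sum_xy += (double)y[i] * x[i]; }

  // proposal scales + acceptance bookkeeping
  double sd_g = 0.3, sd_e = 0.3, sd_a = 0.1, sd_b = 0.1, sd_sg = 0.5,
         sd_se = 0.5, sd_sw = 0.1;
  int acc_g = 0, att_g = 0, acc_e = 0, att_e = 0, acc_a = 0, att_a = 0,
      acc_b = 0, att_b = 0, acc_sg = 0, att_sg = 0, acc_se = 0, att_se = 0,
      acc_sw = 0, att_sw = 0;

  NumericVector keep_alpha(M), keep_beta(M), keep_s2g(M), keep_se(M);
  NumericMatrix keep_gamma(M, N), keep_eps(M, N);

  const int total = n_burn + n_iter;
  int stored = 0;
  for (int sweep = 1; sweep <= total; ++sweep) {
    const bool adapting = sweep <= n_burn;

    // --- gamma: single-site MH against ICAR conditional x likelihood ---
    if (structured) {
      for (int i = 0; i < N; ++i) {
        if (island[i]) continue;
        double m = 0.0;
        for (int p = W_ptr[i]; p < W_ptr[i + 1]; ++p)
          m += W_wt[p] * gam[W_idx[p]];
        m /= W_rowsum[i];
        const double prec = W_rowsum[i] / s2g;
        const double cur = gam[i];
        const double prop = cur + sd_g * norm_rand();
        double lr = -0.5 * prec * ((prop - m) * (prop - m) -
                                   (cur - m) * (cur - m));
        if (use_likelihood) {
          const double off = alpha + beta * x[i] + eps[i];
          lr += y[i] * (prop - cur) -
                E[i] * (std::exp(off + prop) - std::exp(off + cur));
        }
        ++att_g;
        if (std::log(unif_rand()) < lr) { gam[i] = prop; ++acc_g; }
      }
      // recentre live areas to sum to zero; alpha absorbs the mean
      double mg = 0.0;
      for (int i = 0; i < N; ++i) if (!island[i]) mg += gam[i];
      mg /= n_live;
      for (int i = 0; i < N; ++i) if (!island[i]) gam[i] -= mg;
      alpha += mg;
      if (adapting) adapt_scale(sd_g, acc_g, att_g, 0.44);
    }

    // --- eps: single-site MH against N(0, se^2) x likelihood ---
    {
      const double prec_e = 1.0 / (se * se);
      for (int i = 0; i < N; ++i) {
        const double cur = eps[i];
        const double prop = cur + sd_e * norm_rand();
        double lr = -0.5 * prec_e * (prop * prop - cur * cur);
        if (use_likelihood) {
          const double off = alpha + beta * x[i] + gam[i];
          lr += y[i] * (prop - cur) -
                E[i] * (std::exp(off + prop) - std::exp(off + cur));
        }
        ++att_e;
        if (std::log(unif_rand()) < lr) { eps[i] = prop; ++acc_e; }
      }
      if (adapting) adapt_scale(sd_e, acc_e, att_e, 0.44);
    }

    // --- translation moves along likelihood-flat ridges ---
    // The data only inform alpha + eps_i (and beta x_i + eps_i), so the
    // pair (alpha, mean(eps)) forms a ridge the single-site updates walk
    // very slowly. Sample the exact Gaussian conditional along the
    // direction (alpha + c, eps - c), and likewise (beta + t, eps - t x):
    // the likelihood is invariant, only the Gaussian priors enter.
    {
      double sum_e = 0.0;
      for (int i = 0; i < N; ++i) sum_e += eps[i];
      const double prec_c = 1.0 / prior_var_alpha + N / (se * se);
      const double mean_c = (sum_e / (se * se) - alpha / prior_var_alpha) /
                            prec_c;
      const double c = mean_c + norm_rand() / std::sqrt(prec_c);
      alpha += c;
      for (int i = 0; i < N; ++i) eps[i] -= c;
    }
    {
      double sum_ex = 0.0, sum_xx = 0.0;
      for (int i = 0; i < N; ++i) {
        sum_ex += eps[i] * x[i];
        sum_xx += x[i] * x[i];
      }
      if (sum_xx > 0) {
        const double prec_t = 1.0 / prior_var_beta + sum_xx / (se * se);
        const double mean_t = (sum_ex / (se * se) - beta / prior_var_beta) /
                              prec_t;
        const double t = mean_t + norm_rand() / std::sqrt(prec_t);
        beta += t;
        for (int i = 0; i < N; ++i) eps[i] -= t * x[i];
      }
    }

    // (beta + t, gamma - t x_c): spatial confounding between a smooth
    // covariate and the ICAR field is the remaining slow ridge. x is
    // centred so the sum-to-zero constraint is preserved; the ICAR
    // quadratic form is quadratic in t, so the conditional is Gaussian.
    if (structured) {
      bool any_island = false;
      for (int i = 0; i < N; ++i) if (island[i]) { any_island = true; break; }
      if (!any_island) {
        double mx = 0.0;
        for (int i = 0; i < N; ++i) mx += x[i];
        mx /= N;
        double Bq = 0.0, Cq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int p = W_ptr[i]; p < W_ptr[i + 1]; ++p) {
            const int j = W_idx[p];
            const double dg = gam[i] - gam[j];
            const double dx = x[i] - x[j];
            Bq += 0.5 * W_wt[p] * dg * dx;
            Cq += 0.5 * W_wt[p] * dx * dx;
          }
        if (Cq > 0) {
          const double prec_t = 1.0 / prior_var_beta + Cq / s2g;
          const double mean_t = (Bq / s2g - beta / prior_var_beta) / prec_t;
          const double t = mean_t + norm_rand() / std::sqrt(prec_t);
          beta += t;
          for (int i = 0; i < N; ++i) gam[i] -= t * (x[i] - mx);
        }
      }
    }

    // --- alpha: random-walk MH, N(0, prior_var_alpha) prior ---
    {
      const double prop = alpha + sd_a * norm_rand();
      double lr = -0.5 * (prop * prop - alpha * alpha) / prior_var_alpha;
      if (use_likelihood) {
        double S = 0.0;
        for (int i = 0; i < N; ++i)
          S += E[i] * std::exp(alpha + beta * x[i] + gam[i] + eps[i]);
        const double d = prop - alpha;
        lr += sum_y * d - S * (std::exp(d) - 1.0);
      }
      ++att_a;
      if (std::log(unif_rand()) < lr) { alpha = prop; ++acc_a; }
      if (adapting) adapt_scale(sd_a, acc_a, att_a, 0.44);
    }

    // --- beta: random-walk MH, N(0, prior_var_beta) prior ---
    {
      const double prop = beta + sd_b * norm_rand();
      double lr = -0.5 * (prop * prop - beta * beta) / prior_var_beta;
      if (use_likelihood) {
        const double d = prop - beta;
        double S = 0.0;
        for (int i = 0; i < N; ++i) {
          const double mu = E[i] * std::exp(alpha + beta * x[i] + gam[i] +
                                            eps[i]);
          S += mu * (std::exp(d * x[i]) - 1.0);
        }
        lr += sum_xy * d - S;
      }
      ++att_b;
      if (std::log(unif_rand()) < lr) { beta = prop; ++acc_b; }
      if (adapting) adapt_scale(sd_b, acc_b, att_b, 0.44);
    }

    // --- interchange move: transfer mass between eps and gamma ---
    // gamma* = gamma + d*eps_c, eps* = eps - d*eps_c with eps_c the centred
    // eps; eta is unchanged, so only the two priors and the Jacobian
    // |1-d|^(N-1) enter. Counters the gamma/eps confounding of the BYM
    // parameterisation, which single-site updates traverse very slowly.
    if (structured) {
      const double d = sd_sw * norm_rand();
      if (std::fabs(1.0 - d) > 1e-12) {
        double me = 0.0;
        for (int i = 0; i < N; ++i) me += eps[i];
        me /= N;
        std::vector<double> gs(N), es(N);
        for (int i = 0; i < N; ++i) {
          const double ec = eps[i] - me;
          gs[i] = gam[i] + d * ec;
          es[i] = eps[i] - d * ec;
        }
        // keep islands pinned: skip move if it would perturb them
        bool ok = true;
        for (int i = 0; i < N && ok; ++i)
          if (island[i] && std::fabs(gs[i] - gam[i]) > 0) ok = false;
        if (ok) {
          double ss_cur = 0.0, ss_prop = 0.0;
          for (int i = 0; i < N; ++i)
            for (int p = W_ptr[i]; p < W_ptr[i + 1]; ++p) {
              const int j = W_idx[p];
              const double d0 = gam[i] - gam[j], d1 = gs[i] - gs[j];
              ss_cur += 0.5 * W_wt[p] * d0 * d0;
              ss_prop += 0.5 * W_wt[p] * d1 * d1;
            }
          double sse_cur = 0.0, sse_prop = 0.0;
          for (int i = 0; i < N; ++i) {
            sse_cur += eps[i] * eps[i];
            sse_prop += es[i] * es[i];
          }
          double lr = -(ss_prop - ss_cur) / (2.0 * s2g) -
                      (sse_prop - sse_cur) / (2.0 * se * se) +
                      (N - 1) * std::log(std::fabs(1.0 - d));
          ++att_sw;
          if (std::log(unif_rand()) < lr) {
            for (int i = 0; i < N; ++i) { gam[i] = gs[i]; eps[i] = es[i]; }
            // recentre gamma (the transfer moves its mean by d*0 = 0 for
            // centred eps, but guard against numeric drift)
            double mg = 0.0;
            for (int i = 0; i < N; ++i) if (!island[i]) mg += gam[i];
            mg /= n_live;
            for (int i = 0; i < N; ++i) if (!island[i]) gam[i] -= mg;
            alpha += mg;
            ++acc_sw;
          }
          if (adapting) adapt_scale(sd_sw, acc_sw, att_sw, 0.30);
        }
      }
    }

    // --- sigma2_gamma: MH on log scale, exact full conditional ---
    if (structured) {
      double ss = 0.0;  // (1/2) sum_ij w_ij (g_i - g_j)^2, counted once per pair
      for (int i = 0; i < N; ++i)
        for (int p = W_ptr[i]; p < W_ptr[i + 1]; ++p) {
          const int j = W_idx[p];
          const double dg = gam[i] - gam[j];
          ss += 0.5 * W_wt[p] * dg * dg;  // each unordered pair visited twice
        }
      const double th = std::log(s2g);
      const double thp = th + sd_sg * norm_rand();
      const double vp = std::exp(thp);
      // log target in theta: (shape) th - rate e^th - q th - ss/(2 e^th)
      const double lt_cur = sg_shape * th - sg_rate * s2g -
                            icar_exponent * th - ss / (2.0 * s2g);
      const double lt_prop = sg_shape * thp - sg_rate * vp -
                             icar_exponent * thp - ss / (2.0 * vp);
      ++att_sg;
      if (std::log(unif_rand()) < lt_prop - lt_cur) { s2g = vp; ++acc_sg; }
      if (adapting) adapt_scale(sd_sg, acc_sg, att_sg, 0.44);
    }

    // --- sigma_eps: MH on log scale, half-normal prior on the sd ---
    {
      double sse = 0.0;
      for (int i = 0; i < N; ++i) sse += eps[i] * eps[i];
      const double th = std::log(se);
      const double thp = th + sd_se * norm_rand();
      const double sp = std::exp(thp);
      // log target in theta: th - e^{2 th}/(2 nu) - N th - sse/(2 e^{2 th})
      const double lt_cur = th - (se * se) / (2.0 * se_scale2) - N * th -
                            sse / (2.0 * se * se);
      const double lt_prop = thp - (sp * sp) / (2.0 * se_scale2) - N * thp -
                             sse / (2.0 * sp * sp);
      ++att_se;
      if (std::log(unif_rand()) < lt_prop - lt_cur) { se = sp; ++acc_se; }
      if (adapting) adapt_scale(sd_se, acc_se, att_se, 0.44);
    }

    // --- storage ---
    if (sweep > n_burn && (sweep - n_burn) % thin == 0) {
      keep_alpha[stored] = alpha;
      keep_beta[stored] = beta;
      keep_s2g[stored] = s2g;
      keep_se[stored] = se;
      for (int i = 0; i < N; ++i) {
        keep_gamma(stored, i) = gam[i];
        keep_eps(stored, i) = eps[i];
      }
      ++stored;
    }
  }

  return List::create(
    _["alpha"] = keep_alpha, _["beta"] = keep_beta,
    _["gamma"] = keep_gamma, _["epsilon"] = keep_eps,
    _["sigma2_gamma"] = keep_s2g, _["sigma_eps"] = keep_se,
    _["acceptance"] = NumericVector::create(
      _["gamma"] = att_g > 0 ? (double)acc_g / att_g : NA_REAL,
      _["epsilon"] = att_e > 0 ? (double)acc_e / att_e : NA_REAL,
      _["alpha"] = att_a > 0 ? (double)acc_a / att_a : NA_REAL,
      _["beta"] = att_b > 0 ? (double)acc_b / att_b : NA_REAL),
    _["proposal_sd"] = NumericVector::create(
      _["gamma"] = sd_g, _["epsilon"] = sd_e, _["alpha"] = sd_a,
      _["beta"] = sd_b, _["sigma2_gamma"] = sd_sg, _["sigma_eps"] = sd_se));
}
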