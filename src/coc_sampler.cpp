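#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical AR(1) state-space
// model of cross-track deviations.
//
// Observation:  y[j][t] ~ N(x[j][t], se^2)                (t with data)
// Initial:      x[j][0] ~ N(y[j][first obs], (10*se)^2)
// Process:      x[j][t] = gam[j]*x[j][t-1] + sig[j]*T_nu  (scaled t shock)
// Individual:   (1+gam[j])/2 ~ Beta(a_g, b_g),
//               sig[j] ~ Normal(th_g, tau_g^2) truncated to (0, inf)
// Hyper:        a, b, th, tau, nu uniform on configured ranges (per group),
//               se ~ Normal(se_mean, se_sd^2) truncated to (0, inf), shared.
//
// The t shock is represented as a Gamma(nu/2, nu/2) scale mixture of
// normals via auxiliary precisions lam[j][t], which makes the latent states
// conditionally Gaussian so they can be drawn exactly by forward-filter
// backward-sampling.  nu = Inf collapses to the Gaussian model (lam == 1).
//
// Random-walk proposal scales adapt by Robbins-Monro during burn-in only.

struct Adapt {
  std::vector<double> ls;
  void init(int n, double s0) { ls.assign(n, std::log(s0)); }
  void tune(int k, double alpha, int iter) {
    ls[k] += std::pow(iter + 1.0, -0.6) * (alpha - 0.44);
    if (ls[k] < -12.0) ls[k] = -12.0;
    if (ls[k] > 6.0) ls[k] = 6.0;
  }
  double sd(int k) const { return std::exp(ls[k]); }
};

static inline double mh_alpha(double logratio) {
  if (!std::isfinite(logratio)) return 0.0;
  return logratio >= 0.0 ? 1.0 : std::exp(logratio);
}

// [[Rcpp::export]]
List coc_run_chain(List y_list, IntegerVector group, int n_groups,
                   List priors, List init, List fix_spec,
                   int n_iter, int n_burnin, int thin, bool store_states) {
  const int J = y_list.size();
  const int G = n_groups;

  std::vector< std::vector<double> > y(J), x(J), lam(J);
  std::vector< std::vector<bool> > ob(J);
  std::vector<int> Tn(J);
  std::vector<double> a1(J);
  int maxT = 0;
  for (int j = 0; j < J; ++j) {
    NumericVector yj = y_list[j];
    Tn[j] = yj.size();
    if (Tn[j] > maxT) maxT = Tn[j];
    y[j].resize(Tn[j]);
    ob[j].resize(Tn[j]);
    bool found = false;
    for (int t = 0; t < Tn[j]; ++t) {
      y[j][t] = yj[t];
      ob[j][t] = !NumericVector::is_na(yj[t]);
      if (ob[j][t] && !found) { a1[j] = yj[t]; found = true; }
    }
    if (!found) stop("series %d has no observed values", j + 1);
    lam[j].assign(Tn[j], 1.0);
    NumericVector xj = as<NumericVector>(as<List>(init["x"])[j]);
    if ((int) xj.size() != Tn[j]) stop("init state length mismatch");
    x[j].assign(xj.begin(), xj.end());
  }

  // prior bounds / measurement prior
  const double a_lo = priors["a_lo"], a_hi = priors["a_hi"];
  const double b_lo = priors["b_lo"], b_hi = priors["b_hi"];
  const double th_lo = priors["theta_lo"], th_hi = priors["theta_hi"];
  const double tau_lo = priors["tau_lo"], tau_hi = priors["tau_hi"];
  const double nu_lo = priors["nu_lo"], nu_hi = priors["nu_hi"];
  const double se_m = priors["se_mean"], se_s = priors["se_sd"];

  // parameter state
  NumericVector gam = clone(as<NumericVector>(init["gamma"]));
  NumericVector sig = clone(as<NumericVector>(init["sigma"]));
  NumericVector A = clone(as<NumericVector>(init["a"]));
  NumericVector B = clone(as<NumericVector>(init["b"]));
  NumericVector TH = clone(as<NumericVector>(init["theta"]));
  NumericVector TAU = clone(as<NumericVector>(init["tau"]));
  NumericVector NU = clone(as<NumericVector>(init["nu"]));
  double se = as<double>(init["sigma_eps"]);

  const bool up_hyper = !as<bool>(fix_spec["hyper"]);
  const bool up_se = !as<bool>(fix_spec["sigma_eps"]);
  const bool up_gamma = !as<bool>(fix_spec["gamma"]);
  const bool up_nu = up_hyper && !as<bool>(fix_spec["nu"]);

  // adaptation bookkeeping: gamma_j, log sigma_j, then per group
  // (log a, log b, theta, log tau, log nu), then log se
  const int off_hyp = 2 * J;
  const int n_ad = 2 * J + 5 * G + 1;
  Adapt ad;
  ad.init(n_ad, 0.1);
  for (int j = 0; j < J; ++j) ad.ls[j] = std::log(0.03);          // gamma
  for (int j = 0; j < J; ++j) ad.ls[J + j] = std::log(0.25);      // log sigma
  for (int g = 0; g < G; ++g) {
    ad.ls[off_hyp + 5 * g + 2] = std::log(std::max(TAU[g] / 2.0, 0.1));
  }
  ad.ls[n_ad - 1] = std::log(0.01);                               // log se

  const int ndraw = (n_iter - n_burnin + thin - 1) / thin;
  NumericMatrix Dgam(ndraw, J), Dsig(ndraw, J);
  NumericMatrix Da(ndraw, G), Db(ndraw, G), Dth(ndraw, G), Dtau(ndraw, G),
      Dnu(ndraw, G);
  NumericVector Dse(ndraw);
  List Dx(J);
  if (store_states)
    for (int j = 0; j < J; ++j) Dx[j] = NumericMatrix(ndraw, Tn[j]);

  std::vector<double> m(maxT), P(maxT);
  int rec = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();

    // --- 1. auxiliary precisions lam (t scale mixture) --------------------
    for (int j = 0; j < J; ++j) {
      const double nu = NU[group[j]];
      if (!std::isfinite(nu)) continue;
      const double s2 = sig[j] * sig[j];
      for (int t = 1; t < Tn[j]; ++t) {
        const double e = x[j][t] - gam[j] * x[j][t - 1];
        const double rate = 0.5 * (nu + e * e / s2);
        lam[j][t] = R::rgamma(0.5 * (nu + 1.0), 1.0 / rate);
      }
    }

    // --- 2. latent states by FFBS -----------------------------------------
    const double R2 = se * se;
    const double P1 = 100.0 * se * se;
    for (int j = 0; j < J; ++j) {
      const int T = Tn[j];
      const double g = gam[j], s2 = sig[j] * sig[j];
      for (int t = 0; t < T; ++t) {
        double mp, Pp;
        if (t == 0) {
          mp = a1[j];
          Pp = P1;
        } else {
          mp = g * m[t - 1];
          Pp = g * g * P[t - 1] + s2 / lam[j][t];
        }
        if (ob[j][t]) {
          const double K = Pp / (Pp + R2);
          m[t] = mp + K * (y[j][t] - mp);
          P[t] = (1.0 - K) * Pp;
        } else {
          m[t] = mp;
          P[t] = Pp;
        }
      }
      x[j][T - 1] = R::rnorm(m[T - 1], std::sqrt(P[T - 1]));
      for (int t = T - 2; t >= 0; --t) {
        const double q1 = s2 / lam[j][t + 1];
        const double den = g * g * P[t] + q1;
        const double Bk = g * P[t] / den;
        const double mu = m[t] + Bk * (x[j][t + 1] - g * m[t]);
        double vv = P[t] - Bk * g * P[t];
        if (vv < 0.0) vv = 0.0;
        x[j][t] = R::rnorm(mu, std::sqrt(vv));
      }
    }

    // --- 3. gamma_j (random walk on the Fisher-z scale) --------------------
    if (up_gamma) {
      for (int j = 0; j < J; ++j) {
        const double sdp = ad.sd(j);
        const double g0 = gam[j];
        const double z0 = std::atanh(g0);
        const double zp = z0 + R::rnorm(0.0, sdp);
        const double gp = std::tanh(zp);
        double alpha = 0.0;
        if (std::fabs(gp) < 1.0) {
          const double s2 = sig[j] * sig[j];
          double d = 0.0;
          for (int t = 1; t < Tn[j]; ++t) {
            const double e0 = x[j][t] - g0 * x[j][t - 1];
            const double e1 = x[j][t] - gp * x[j][t - 1];
            d += -0.5 * lam[j][t] * (e1 * e1 - e0 * e0) / s2;
          }
          const int g = group[j];
          d += (A[g] - 1.0) * (std::log1p(gp) - std::log1p(g0)) +
               (B[g] - 1.0) * (std::log1p(-gp) - std::log1p(-g0));
          // Jacobian dgamma/dz = 1 - gamma^2
          d += std::log1p(-gp * gp) - std::log1p(-g0 * g0);
          alpha = mh_alpha(d);
          if (R::unif_rand() < alpha) gam[j] = gp;
        }
        if (iter < n_burnin) ad.tune(j, alpha, iter);
      }
    }

    // --- 4. sigma_j (log scale) --------------------------------------------
    for (int j = 0; j < J; ++j) {
      const double sdp = ad.sd(J + j);
      const double s0 = sig[j];
      const double ls0 = std::log(s0);
      const double lsp = ls0 + R::rnorm(0.0, sdp);
      const double sp = std::exp(lsp);
      double S = 0.0;
      for (int t = 1; t < Tn[j]; ++t) {
        const double e = x[j][t] - gam[j] * x[j][t - 1];
        S += lam[j][t] * e * e;
      }
      const int g = group[j];
      const double Tm1 = Tn[j] - 1.0;
      const double ll0 = -Tm1 * ls0 - 0.5 * S / (s0 * s0) -
                         0.5 * std::pow((s0 - TH[g]) / TAU[g], 2) + ls0;
      const double ll1 = -Tm1 * lsp - 0.5 * S / (sp * sp) -
                         0.5 * std::pow((sp - TH[g]) / TAU[g], 2) + lsp;
      const double alpha = mh_alpha(ll1 - ll0);
      if (R::unif_rand() < alpha) sig[j] = sp;
      if (iter < n_burnin) ad.tune(J + j, alpha, iter);
    }

    // --- 5. group-level hyper-parameters -----------------------------------
    if (up_hyper) {
      for (int g = 0; g < G; ++g) {
        // beta shapes via (logit mean, log concentration): the posterior
        // of (a, b) is a narrow ridge in the raw coordinates
        {
          const double a0 = A[g], b0 = B[g];
          const double m0 = a0 / (a0 + b0), c0 = a0 + b0;
          // move 1: logit mean, concentration held
          {
            const int k = off_hyp + 5 * g;
            const double u0 = std::log(m0 / (1.0 - m0));
            const double up = u0 + R::rnorm(0.0, ad.sd(k));
            const double mp = 1.0 / (1.0 + std::exp(-up));
            const double ap = mp * c0, bp = (1.0 - mp) * c0;
            double alpha = 0.0;
            if (ap >= a_lo && ap <= a_hi && bp >= b_lo && bp <= b_hi) {
              double d = std::log(mp) + std::log1p(-mp) -
                         std::log(m0) - std::log1p(-m0);  // Jacobian
              for (int j = 0; j < J; ++j) {
                if (group[j] != g) continue;
                const double v = 0.5 * (1.0 + gam[j]);
                d += R::dbeta(v, ap, bp, 1) - R::dbeta(v, A[g], B[g], 1);
              }
              alpha = mh_alpha(d);
              if (R::unif_rand() < alpha) { A[g] = ap; B[g] = bp; }
            }
            if (iter < n_burnin) ad.tune(k, alpha, iter);
          }
          // move 2: log concentration, mean held
          {
            const int k = off_hyp + 5 * g + 1;
            const double m1 = A[g] / (A[g] + B[g]), c1 = A[g] + B[g];
            const double cp = std::exp(std::log(c1) +
                                       R::rnorm(0.0, ad.sd(k)));
            const double ap = m1 * cp, bp = (1.0 - m1) * cp;
            double alpha = 0.0;
            if (ap >= a_lo && ap <= a_hi && bp >= b_lo && bp <= b_hi) {
              double d = 2.0 * (std::log(cp) - std::log(c1));  // Jacobian
              for (int j = 0; j < J; ++j) {
                if (group[j] != g) continue;
                const double v = 0.5 * (1.0 + gam[j]);
                d += R::dbeta(v, ap, bp, 1) - R::dbeta(v, A[g], B[g], 1);
              }
              alpha = mh_alpha(d);
              if (R::unif_rand() < alpha) { A[g] = ap; B[g] = bp; }
            }
            if (iter < n_burnin) ad.tune(k, alpha, iter);
          }
        }
        // truncated-normal location theta (linear RW)
        {
          const int k = off_hyp + 5 * g + 2;
          const double t0 = TH[g];
          const double tp = t0 + R::rnorm(0.0, ad.sd(k));
          double alpha = 0.0;
          if (tp >= th_lo && tp <= th_hi) {
            double d = 0.0;
            for (int j = 0; j < J; ++j) {
              if (group[j] != g) continue;
              d += R::dnorm(sig[j], tp, TAU[g], 1) -
                   R::dnorm(sig[j], t0, TAU[g], 1);
            }
            // truncation normalizer Phi(theta/tau) per individual
            int ng = 0;
            for (int j = 0; j < J; ++j) if (group[j] == g) ++ng;
            d -= ng * (R::pnorm(tp / TAU[g], 0.0, 1.0, 1, 1) -
                       R::pnorm(t0 / TAU[g], 0.0, 1.0, 1, 1));
            alpha = mh_alpha(d);
            if (R::unif_rand() < alpha) TH[g] = tp;
          }
          if (iter < n_burnin) ad.tune(k, alpha, iter);
        }
        // truncated-normal scale tau (log RW)
        {
          const int k = off_hyp + 5 * g + 3;
          const double t0 = TAU[g];
          const double tp = std::exp(std::log(t0) + R::rnorm(0.0, ad.sd(k)));
          double alpha = 0.0;
          if (tp >= tau_lo && tp <= tau_hi) {
            double d = std::log(tp) - std::log(t0);
            int ng = 0;
            for (int j = 0; j < J; ++j) {
              if (group[j] != g) continue;
              ++ng;
              d += R::dnorm(sig[j], TH[g], tp, 1) -
                   R::dnorm(sig[j], TH[g], t0, 1);
            }
            d -= ng * (R::pnorm(TH[g] / tp, 0.0, 1.0, 1, 1) -
                       R::pnorm(TH[g] / t0, 0.0, 1.0, 1, 1));
            alpha = mh_alpha(d);
            if (R::unif_rand() < alpha) TAU[g] = tp;
          }
          if (iter < n_burnin) ad.tune(k, alpha, iter);
        }
        // degrees of freedom nu (log RW), via the mixing precisions
        if (up_nu && std::isfinite(NU[g])) {
          const int k = off_hyp + 5 * g + 4;
          const double n0 = NU[g];
          const double np = std::exp(std::log(n0) + R::rnorm(0.0, ad.sd(k)));
          double alpha = 0.0;
          if (np >= nu_lo && np <= nu_hi) {
            double Slog = 0.0, Ssum = 0.0;
            double ne = 0.0;
            for (int j = 0; j < J; ++j) {
              if (group[j] != g) continue;
              for (int t = 1; t < Tn[j]; ++t) {
                Slog += std::log(lam[j][t]);
                Ssum += lam[j][t];
                ne += 1.0;
              }
            }
            const double h0 = 0.5 * n0, hp = 0.5 * np;
            double d = ne * (hp * std::log(hp) - std::lgamma(hp) -
                             h0 * std::log(h0) + std::lgamma(h0)) +
                       (hp - h0) * Slog - (hp - h0) * Ssum;
            d += std::log(np) - std::log(n0);
            alpha = mh_alpha(d);
            if (R::unif_rand() < alpha) NU[g] = np;
          }
          if (iter < n_burnin) ad.tune(k, alpha, iter);
        }
      }
    }

    // --- 6. shared measurement SD sigma_eps (log RW) -----------------------
    if (up_se) {
      const int k = n_ad - 1;
      const double s0 = se;
      const double sp = std::exp(std::log(s0) + R::rnorm(0.0, ad.sd(k)));
      double d = std::log(sp) - std::log(s0);
      for (int j = 0; j < J; ++j) {
        for (int t = 0; t < Tn[j]; ++t) {
          if (!ob[j][t]) continue;
          d += R::dnorm(y[j][t], x[j][t], sp, 1) -
               R::dnorm(y[j][t], x[j][t], s0, 1);
        }
        d += R::dnorm(x[j][0], a1[j], 10.0 * sp, 1) -
             R::dnorm(x[j][0], a1[j], 10.0 * s0, 1);
      }
      d += R::dnorm(sp, se_m, se_s, 1) - R::dnorm(s0, se_m, se_s, 1);
      const double alpha = mh_alpha(d);
      if (R::unif_rand() < alpha) se = sp;
      if (iter < n_burnin) ad.tune(k, alpha, iter);
    }

    // --- 7. record ----------------------------------------------------------
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0) {
      for (int j = 0; j < J; ++j) {
        Dgam(rec, j) = gam[j];
        Dsig(rec, j) = sig[j];
      }
      for (int g = 0; g < G; ++g) {
        Da(rec, g) = A[g];
        Db(rec, g) = B[g];
        Dth(rec, g) = TH[g];
        Dtau(rec, g) = TAU[g];
        Dnu(rec, g) = NU[g];
      }
      Dse[rec] = se;
      if (store_states) {
        for (int j = 0; j < J; ++j) {
          NumericMatrix Xj = Dx[j];
          for (int t = 0; t < Tn[j]; ++t) Xj(rec, t) = x[j][t];
        }
      }
      ++rec;
    }
  }

  return List::create(
      _["gamma"] = Dgam, _["sigma"] = Dsig, _["a"] = Da, _["b"] = Db,
      _["theta"] = Dth, _["tau"] = Dtau, _["nu"] = Dnu, _["sigma_eps"] = Dse,
      _["states"] = store_states ? (SEXP) Dx : R_NilValue,
      _["n_retained"] = rec);
}
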