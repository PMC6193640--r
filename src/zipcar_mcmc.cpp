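// Adaptive random-walk Metropolis-within-Gibbs sampler for the
// zero-inflated Poisson model with an intrinsic-CAR structured effect and
// an exchangeable unstructured effect:
//   log mu_i    = offset_i + x_i'beta + v_i + u_i
//   logit pi_i  = x_i'gamma                  (zip = true only)
//   y_i ~ pi_i * 1{0} + (1 - pi_i) * Poisson(mu_i)
// The mixture is used directly (no latent-indicator augmentation), so the
// chain targets the posterior of exactly the likelihood the DIC reports.
// Priors: beta_j, gamma_j ~ N(0, prior_sd^2); the effect scales carry
// either penalized-complexity priors sigma ~ Exponential(sigma_rate)
// (default; sampled by MH on log tau) or conjugate Gamma(a, b) priors on
// the precisions;
// v | tau_v ~ ICAR(W), constrained to sum to zero within each graph
// component (re-centered every sweep). Several likelihood-invariant
// interweaving moves (intercept/u shift, v/u swap, effect-precision
// rescalings) handle the weakly identified directions. Uses R's RNG so
// results are fully reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double rw_adapt(double ls, double acc, double target,
                              int iter) {
  return ls + (acc - target) / std::sqrt(iter + 1.0);
}

// per-state log-likelihood term (y! constant dropped for y > 0)
static inline double ll_term(double eta, double lp, int y, bool zip) {
  double pois = y * eta - std::exp(eta);
  if (!zip) return pois;
  double l1pe = R::log1pexp(lp);     // log(1 + e^lp)
  if (y > 0) return -l1pe + pois;    // log(1-pi) + Poisson
  double lpi = lp - l1pe;            // log pi
  double lq = -l1pe - std::exp(eta); // log((1-pi) e^{-mu})
  double m = std::max(lpi, lq);
  return m + std::log(std::exp(lpi - m) + std::exp(lq - m));
}

// log hyperprior density of a precision (constants dropped):
// PC: sigma ~ Exp(rate)  =>  p(tau) ~ exp(-rate/sqrt(tau)) * tau^{-3/2}
// Gamma: p(tau) ~ tau^{shape-1} exp(-rate_g * tau)
static inline double log_tau_prior(double tau, bool pc, double sigma_rate,
                                   double shape, double rate_g) {
  if (pc) return -sigma_rate / std::sqrt(tau) - 1.5 * std::log(tau);
  return (shape - 1.0) * std::log(tau) - rate_g * tau;
}

// [[Rcpp::export(name = ".zipcar_chain")]]
List zipcar_chain(IntegerVector y, NumericMatrix X, NumericVector offset,
                  List nb, IntegerVector deg, IntegerVector comp_id,
                  bool zip, int n_iter, int n_burn, int thin,
                  double prior_sd, bool pc_prior, double sigma_rate,
                  double tau_shape, double tau_rate, double beta0_init) {
  int n = y.size(), p = X.ncol();
  RNGScope scope;

  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) nbr[i] = as<std::vector<int>>(nb[i]);

  int n_comp = 0;
  for (int i = 0; i < n; ++i) n_comp = std::max(n_comp, comp_id[i]);
  std::vector<std::vector<int>> comps(n_comp);
  for (int i = 0; i < n; ++i) comps[comp_id[i] - 1].push_back(i);
  int icar_rank = 0;
  for (int c = 0; c < n_comp; ++c)
    if (comps[c].size() > 1) icar_rank += comps[c].size() - 1;

  NumericVector beta(p), gamma(p), v(n), u(n);
  double tau_v = 1.0, tau_u = 1.0;
  // precisions stay at 1 early in warm-up so the effect vectors can adapt
  // to the residuals first; otherwise the first conjugate draw (taken from
  // u = v = 0) pins both vectors at zero for good
  int tau_freeze = std::min(500, n_burn / 4);

  beta[0] = beta0_init;
  for (int i = 0; i < n; ++i) {
    u[i] = 0.1 * R::norm_rand();
    if (deg[i] > 0) v[i] = 0.1 * R::norm_rand();
  }

  NumericVector eta(n), xg(n), ll(n);
  for (int i = 0; i < n; ++i) {
    eta[i] = offset[i] + beta[0] + v[i] + u[i];
    ll[i] = ll_term(eta[i], xg[i], y[i], zip);
  }

  NumericVector ls_b(p, -1.0), ls_g(p, -1.0), ls_v(n, -1.0), ls_u(n, -1.0),
      ls_w(n, -1.0);
  double ls_shift = -1.0, ls_scale_u = -1.0, ls_scale_v = -1.0,
         ls_fun_u = -1.0, ls_fun_v = -1.0, ls_tau_v = -1.0, ls_tau_u = -1.0;
  double acc_b = 0, try_b = 0, acc_g = 0, try_g = 0,
         acc_v = 0, try_v = 0, acc_u = 0, try_u = 0;

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out_beta(n_keep, p), out_gamma(n_keep, zip ? p : 0),
      out_v(n_keep, n), out_u(n_keep, n);
  NumericVector out_tau_v(n_keep), out_tau_u(n_keep);
  int keep = 0;

  NumericVector eta_new(n), ll_new(n);

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_burn;

    // --- beta: single-site random walk ------------------------------------
    for (int j = 0; j < p; ++j) {
      double db = std::exp(ls_b[j]) * R::norm_rand();
      double dll = (beta[j] * beta[j] -
                    (beta[j] + db) * (beta[j] + db)) /
                   (2 * prior_sd * prior_sd);
      for (int i = 0; i < n; ++i) {
        eta_new[i] = eta[i] + X(i, j) * db;
        ll_new[i] = ll_term(eta_new[i], xg[i], y[i], zip);
        dll += ll_new[i] - ll[i];
      }
      ++try_b;
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        beta[j] += db;
        for (int i = 0; i < n; ++i) { eta[i] = eta_new[i]; ll[i] = ll_new[i]; }
        ++acc_b;
      }
      if (adapting) ls_b[j] = rw_adapt(ls_b[j], acc, 0.44, it);
    }

    // --- gamma: single-site random walk on the zero model ------------------
    if (zip) {
      for (int j = 0; j < p; ++j) {
        double dg = std::exp(ls_g[j]) * R::norm_rand();
        double dll = (gamma[j] * gamma[j] -
                      (gamma[j] + dg) * (gamma[j] + dg)) /
                     (2 * prior_sd * prior_sd);
        for (int i = 0; i < n; ++i) {
          ll_new[i] = ll_term(eta[i], xg[i] + X(i, j) * dg, y[i], zip);
          dll += ll_new[i] - ll[i];
        }
        ++try_g;
        int acc = std::log(R::unif_rand()) < dll;
        if (acc) {
          gamma[j] += dg;
          for (int i = 0; i < n; ++i) {
            xg[i] += X(i, j) * dg;
            ll[i] = ll_new[i];
          }
          ++acc_g;
        }
        if (adapting) ls_g[j] = rw_adapt(ls_g[j], acc, 0.44, it);
      }
    }

    // --- v: single-site RW under the ICAR full conditional ------------------
    for (int i = 0; i < n; ++i) {
      if (deg[i] == 0) continue;  // isolated: v pinned at 0
      double nbar = 0.0;
      for (int k : nbr[i]) nbar += v[k];
      nbar /= deg[i];
      double dv = std::exp(ls_v[i]) * R::norm_rand();
      double vn = v[i] + dv;
      double lln = ll_term(eta[i] + dv, xg[i], y[i], zip);
      double dll = -0.5 * tau_v * deg[i] *
                       ((vn - nbar) * (vn - nbar) -
                        (v[i] - nbar) * (v[i] - nbar)) +
                   lln - ll[i];
      ++try_v;
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) { v[i] = vn; eta[i] += dv; ll[i] = lln; ++acc_v; }
      if (adapting) ls_v[i] = rw_adapt(ls_v[i], acc, 0.44, it);
    }

    // --- u: single-site RW ---------------------------------------------------
    for (int i = 0; i < n; ++i) {
      double du = std::exp(ls_u[i]) * R::norm_rand();
      double un = u[i] + du;
      double lln = ll_term(eta[i] + du, xg[i], y[i], zip);
      double dll = -0.5 * tau_u * (un * un - u[i] * u[i]) + lln - ll[i];
      ++try_u;
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) { u[i] = un; eta[i] += du; ll[i] = lln; ++acc_u; }
      if (adapting) ls_u[i] = rw_adapt(ls_u[i], acc, 0.44, it);
    }

    // --- swap interweave: v_i += d, u_i -= d (likelihood-invariant) ---------
    // only v_i + u_i is likelihood-identified; this moves the split
    for (int i = 0; i < n; ++i) {
      if (deg[i] == 0) continue;
      double d = std::exp(ls_w[i]) * R::norm_rand();
      double nbar = 0.0;
      for (int k : nbr[i]) nbar += v[k];
      nbar /= deg[i];
      double vn = v[i] + d, un = u[i] - d;
      double dll = -0.5 * tau_v * deg[i] *
                       ((vn - nbar) * (vn - nbar) -
                        (v[i] - nbar) * (v[i] - nbar)) -
                   0.5 * tau_u * (un * un - u[i] * u[i]);
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) { v[i] = vn; u[i] = un; }
      if (adapting) ls_w[i] = rw_adapt(ls_w[i], acc, 0.44, it);
    }

    // re-center per component (ICAR sum-to-zero constraint); eta invariant
    // because the mean is moved between v and the per-state totals only by
    // subtracting it from both v and eta
    for (int c = 0; c < n_comp; ++c) {
      if (comps[c].size() < 2) continue;
      double m = 0.0;
      for (int i : comps[c]) m += v[i];
      m /= comps[c].size();
      for (int i : comps[c]) {
        v[i] -= m;
        eta[i] -= m;
        ll[i] = ll_term(eta[i], xg[i], y[i], zip);
      }
    }

    // --- interweaving shift: beta0 += d, u -= d (likelihood-invariant) ------
    {
      double d = std::exp(ls_shift) * R::norm_rand();
      double b0 = beta[0], b0n = b0 + d;
      double su = 0.0;
      for (int i = 0; i < n; ++i) su += u[i];
      double dll = (b0 * b0 - b0n * b0n) / (2 * prior_sd * prior_sd) -
                   0.5 * tau_u * (n * d * d - 2.0 * d * su);
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        beta[0] = b0n;
        for (int i = 0; i < n; ++i) u[i] -= d;
      }
      if (adapting) ls_shift = rw_adapt(ls_shift, acc, 0.44, it);
    }

    // --- scale move u -> c*u (tau fixed) ------------------------------------
    {
      double dl = std::exp(ls_scale_u) * R::norm_rand();
      double c = std::exp(dl);
      double su2 = 0.0;
      for (int i = 0; i < n; ++i) su2 += u[i] * u[i];
      double dll = n * dl - 0.5 * tau_u * (c * c - 1.0) * su2;
      for (int i = 0; i < n; ++i) {
        eta_new[i] = eta[i] + (c - 1.0) * u[i];
        ll_new[i] = ll_term(eta_new[i], xg[i], y[i], zip);
        dll += ll_new[i] - ll[i];
      }
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        for (int i = 0; i < n; ++i) {
          eta[i] = eta_new[i]; ll[i] = ll_new[i]; u[i] *= c;
        }
      }
      if (adapting) ls_scale_u = rw_adapt(ls_scale_u, acc, 0.23, it);
    }

    // --- funnel moves: (u, tau_u) -> (c*u, tau_u/c^2), same for (v, tau_v)
    // the Gaussian prior is invariant under this rescaling, so the move
    // travels along the funnel axis the Gibbs steps cannot traverse
    {
      double dl = std::exp(ls_fun_u) * R::norm_rand();
      double c = std::exp(dl);
      double tau_n = tau_u / (c * c);
      // Gaussian prior x Jacobian reduces to c^{-2}; add hyperprior ratio
      double dll = -2.0 * dl +
                   log_tau_prior(tau_n, pc_prior, sigma_rate, tau_shape,
                                 tau_rate) -
                   log_tau_prior(tau_u, pc_prior, sigma_rate, tau_shape,
                                 tau_rate);
      for (int i = 0; i < n; ++i) {
        eta_new[i] = eta[i] + (c - 1.0) * u[i];
        ll_new[i] = ll_term(eta_new[i], xg[i], y[i], zip);
        dll += ll_new[i] - ll[i];
      }
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        for (int i = 0; i < n; ++i) {
          eta[i] = eta_new[i]; ll[i] = ll_new[i]; u[i] *= c;
        }
        tau_u = tau_n;
      }
      if (adapting) ls_fun_u = rw_adapt(ls_fun_u, acc, 0.23, it);
    }
    {
      double dl = std::exp(ls_fun_v) * R::norm_rand();
      double c = std::exp(dl);
      double tau_n = tau_v / (c * c);
      double dll = -2.0 * dl +
                   log_tau_prior(tau_n, pc_prior, sigma_rate, tau_shape,
                                 tau_rate) -
                   log_tau_prior(tau_v, pc_prior, sigma_rate, tau_shape,
                                 tau_rate);
      for (int i = 0; i < n; ++i) {
        eta_new[i] = eta[i] + (c - 1.0) * v[i];
        ll_new[i] = ll_term(eta_new[i], xg[i], y[i], zip);
        dll += ll_new[i] - ll[i];
      }
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        for (int i = 0; i < n; ++i) {
          eta[i] = eta_new[i]; ll[i] = ll_new[i]; v[i] *= c;
        }
        tau_v = tau_n;
      }
      if (adapting) ls_fun_v = rw_adapt(ls_fun_v, acc, 0.23, it);
    }

    // --- scale move v -> c*v (tau fixed) ------------------------------------
    {
      double dl = std::exp(ls_scale_v) * R::norm_rand();
      double c = std::exp(dl);
      double ssv = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k : nbr[i]) ssv += (v[i] - v[k]) * (v[i] - v[k]);
      ssv *= 0.25;
      double dll = icar_rank * dl - tau_v * (c * c - 1.0) * ssv;
      for (int i = 0; i < n; ++i) {
        eta_new[i] = eta[i] + (c - 1.0) * v[i];
        ll_new[i] = ll_term(eta_new[i], xg[i], y[i], zip);
        dll += ll_new[i] - ll[i];
      }
      int acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        for (int i = 0; i < n; ++i) {
          eta[i] = eta_new[i]; ll[i] = ll_new[i]; v[i] *= c;
        }
      }
      if (adapting) ls_scale_v = rw_adapt(ls_scale_v, acc, 0.23, it);
    }

    // --- precisions ----------------------------------------------------------
    if (it >= tau_freeze) {
      double ss_v = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k : nbr[i]) ss_v += (v[i] - v[k]) * (v[i] - v[k]);
      ss_v *= 0.25;  // each edge counted twice; pairwise ICAR kernel is 1/2
      double ss_u = 0.0;
      for (int i = 0; i < n; ++i) ss_u += u[i] * u[i];
      if (!pc_prior) {  // conjugate Gamma updates
        tau_v = R::rgamma(tau_shape + 0.5 * icar_rank,
                          1.0 / (tau_rate + ss_v));
        tau_u = R::rgamma(tau_shape + 0.5 * n,
                          1.0 / (tau_rate + 0.5 * ss_u));
      } else {          // MH on log tau under the PC prior
        auto tau_mh = [&](double tau, double k_half, double ss,
                          double &ls) {
          double lt = std::log(tau);
          double ltn = lt + std::exp(ls) * R::norm_rand();
          double tn = std::exp(ltn);
          // Gaussian kernel + hyperprior + log-scale Jacobian
          double dll = k_half * (ltn - lt) - (tn - tau) * ss +
                       log_tau_prior(tn, true, sigma_rate, 0, 0) -
                       log_tau_prior(tau, true, sigma_rate, 0, 0) +
                       (ltn - lt);
          int acc = std::log(R::unif_rand()) < dll;
          if (adapting) ls = rw_adapt(ls, acc, 0.44, it);
          return acc ? tn : tau;
        };
        tau_v = tau_mh(tau_v, 0.5 * icar_rank, ss_v, ls_tau_v);
        tau_u = tau_mh(tau_u, 0.5 * n, 0.5 * ss_u, ls_tau_u);
      }
    }

    // --- store ---------------------------------------------------------------
    if (it >= n_burn && (it - n_burn) % thin == 0 && keep < n_keep) {
      for (int j = 0; j < p; ++j) out_beta(keep, j) = beta[j];
      if (zip) for (int j = 0; j < p; ++j) out_gamma(keep, j) = gamma[j];
      for (int i = 0; i < n; ++i) {
        out_v(keep, i) = v[i];
        out_u(keep, i) = u[i];
      }
      out_tau_v[keep] = tau_v;
      out_tau_u[keep] = tau_u;
      ++keep;
    }
  }

  return List::create(
      _["beta"] = out_beta, _["gamma"] = out_gamma, _["v"] = out_v,
      _["u"] = out_u, _["tau_v"] = out_tau_v, _["tau_u"] = out_tau_u,
      _["accept"] = NumericVector::create(
          _["beta"] = acc_b / std::max(try_b, 1.0),
          _["gamma"] = zip ? acc_g / std::max(try_g, 1.0) : NA_REAL,
          _["v"] = acc_v / std::max(try_v, 1.0),
          _["u"] = acc_u / std::max(try_u, 1.0)));
}
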