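// Adaptive Metropolis-within-Gibbs sampler for the negative binomial model
// with log-area offset and optional ICAR spatial random effect.
//
// Blocks per sweep: single-site adaptive random-walk updates for each fixed
// effect, a random-walk update for log(theta), single-site updates for each
// spatial effect z_i using the ICAR full conditional prior, sum-to-zero
// recentering of z per graph component, and a conjugate gamma draw for tau.
// Proposal scales adapt toward 44% acceptance during burn-in only, so the
// post-burn-in chain is a valid Markov chain.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// log NB(y | mu = exp(eta), theta) summed over the years of one cell
inline double cell_loglik(const IntegerMatrix &y, const NumericMatrix &lgyf,
                          int c, double eta, double theta,
                          double lgamma_theta, double log_theta) {
  const int n_years = y.ncol();
  const double log_mu_theta = R::log1pexp(eta - log_theta) + log_theta;
  // log(mu + theta) computed stably as log_theta + log1p(exp(eta - log_theta))
  double out = 0.0;
  for (int t = 0; t < n_years; ++t) {
    const double yy = (double) y(c, t);
    out += lgamma(yy + theta) - lgamma_theta - lgyf(c, t) +
      yy * (eta - log_mu_theta) + theta * (log_theta - log_mu_theta);
  }
  return out;
}

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

} // namespace

// [[Rcpp::export(name = ".nbicar_chain")]]
List nbicar_chain(IntegerMatrix y,            // n_cells x n_years counts
                  NumericMatrix X,            // n_cells x p design
                  NumericVector log_offset,   // per cell
                  IntegerVector region_index, // 1-based, per cell
                  int n_regions,
                  List region_cells,          // per region: 1-based cell ids
                  List neighbours,            // per region: 1-based neighbours
                  IntegerVector component,    // per region component label
                  int n_components,
                  IntegerMatrix edges,        // 1-based region pairs (m x 2)
                  bool include_icar,
                  double alpha_sd, double lt_mean, double lt_sd,
                  double tau_shape, double tau_rate,
                  NumericVector alpha_init, double log_theta_init,
                  NumericVector z_init, double tau_init,
                  int n_iter, int n_burn, int thin,
                  bool fix_theta, bool fix_tau) {
  const int n_cells = y.nrow();
  const int p = X.ncol();
  RNGScope scope;

  // parameter state
  NumericVector alpha = clone(alpha_init);
  double log_theta = log_theta_init;
  double theta = exp(log_theta);
  NumericVector z = clone(z_init);
  double tau = tau_init;

  // column supports: cells where X(., j) != 0
  std::vector< std::vector<int> > support(p);
  for (int j = 0; j < p; ++j)
    for (int c = 0; c < n_cells; ++c)
      if (X(c, j) != 0.0) support[j].push_back(c);

  // lgamma(y + 1), fixed
  NumericMatrix lgyf(n_cells, y.ncol());
  for (int c = 0; c < n_cells; ++c)
    for (int t = 0; t < y.ncol(); ++t)
      lgyf(c, t) = lgamma((double) y(c, t) + 1.0);

  // linear predictor and cached per-cell log-likelihood
  NumericVector eta(n_cells);
  for (int c = 0; c < n_cells; ++c) {
    double v = log_offset[c];
    for (int j = 0; j < p; ++j) v += X(c, j) * alpha[j];
    if (include_icar) v += z[region_index[c] - 1];
    eta[c] = v;
  }
  double lgamma_theta = lgamma(theta);
  NumericVector cll(n_cells);
  for (int c = 0; c < n_cells; ++c)
    cll[c] = cell_loglik(y, lgyf, c, eta[c], theta, lgamma_theta, log_theta);

  // adaptive proposal scales
  NumericVector sd_a(p, 0.1), sd_z(n_regions, 0.1);
  double sd_t = 0.1;
  NumericVector acc_a(p), acc_z(n_regions);
  double acc_t = 0.0;
  const int adapt_window = 50;
  const double target = 0.44;

  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out_alpha(n_keep, p);
  NumericVector out_lt(n_keep), out_tau(n_keep), out_ll(n_keep);
  NumericMatrix out_z(include_icar ? n_keep : 0,
                      include_icar ? n_regions : 0);

  double total_acc_a = 0.0, total_acc_z = 0.0, total_acc_t = 0.0;
  long n_prop_a = 0, n_prop_z = 0, n_prop_t = 0;
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- fixed effects, single-site adaptive random walk ---
    for (int j = 0; j < p; ++j) {
      const double prop = alpha[j] + sd_a[j] * norm_rand();
      const double delta = prop - alpha[j];
      double log_acc = (R::dnorm(prop, 0.0, alpha_sd, 1) -
                        R::dnorm(alpha[j], 0.0, alpha_sd, 1));
      const std::vector<int> &sup = support[j];
      std::vector<double> new_ll(sup.size());
      for (size_t s = 0; s < sup.size(); ++s) {
        const int c = sup[s];
        new_ll[s] = cell_loglik(y, lgyf, c, eta[c] + delta * X(c, j), theta,
                                lgamma_theta, log_theta);
        log_acc += new_ll[s] - cll[c];
      }
      ++n_prop_a;
      if (log(unif_rand()) < log_acc) {
        alpha[j] = prop;
        for (size_t s = 0; s < sup.size(); ++s) {
          const int c = sup[s];
          eta[c] += delta * X(c, j);
          cll[c] = new_ll[s];
        }
        acc_a[j] += 1.0;
        total_acc_a += 1.0;
      }
    }

    // --- log(theta), random walk ---
    if (!fix_theta) {
      const double prop_lt = log_theta + sd_t * norm_rand();
      const double prop_theta = exp(prop_lt);
      const double prop_lgt = lgamma(prop_theta);
      double log_acc = (R::dnorm(prop_lt, lt_mean, lt_sd, 1) -
                        R::dnorm(log_theta, lt_mean, lt_sd, 1));
      NumericVector new_cll(n_cells);
      for (int c = 0; c < n_cells; ++c) {
        new_cll[c] = cell_loglik(y, lgyf, c, eta[c], prop_theta, prop_lgt,
                                 prop_lt);
        log_acc += new_cll[c] - cll[c];
      }
      ++n_prop_t;
      if (log(unif_rand()) < log_acc) {
        log_theta = prop_lt;
        theta = prop_theta;
        lgamma_theta = prop_lgt;
        cll = new_cll;
        acc_t += 1.0;
        total_acc_t += 1.0;
      }
    }

    if (include_icar) {
      // --- spatial effects, single-site with ICAR full-conditional prior ---
      for (int r = 0; r < n_regions; ++r) {
        const double prop = z[r] + sd_z[r] * norm_rand();
        const double delta = prop - z[r];
        const IntegerVector nb = neighbours[r];
        double prior_delta = 0.0;
        for (int q = 0; q < nb.size(); ++q) {
          const double zj = z[nb[q] - 1];
          prior_delta += (prop - zj) * (prop - zj) - (z[r] - zj) * (z[r] - zj);
        }
        double log_acc = -(tau / 2.0) * prior_delta;
        const IntegerVector rc = region_cells[r];
        std::vector<double> new_ll(rc.size());
        for (int s = 0; s < rc.size(); ++s) {
          const int c = rc[s] - 1;
          new_ll[s] = cell_loglik(y, lgyf, c, eta[c] + delta, theta,
                                  lgamma_theta, log_theta);
          log_acc += new_ll[s] - cll[c];
        }
        ++n_prop_z;
        if (log(unif_rand()) < log_acc) {
          z[r] = prop;
          for (int s = 0; s < rc.size(); ++s) {
            const int c = rc[s] - 1;
            eta[c] += delta;
            cll[c] = new_ll[s];
          }
          acc_z[r] += 1.0;
          total_acc_z += 1.0;
        }
      }

      // --- sum-to-zero recentering per component ---
      std::vector<double> comp_sum(n_components, 0.0);
      std::vector<int> comp_n(n_components, 0);
      for (int r = 0; r < n_regions; ++r) {
        comp_sum[component[r] - 1] += z[r];
        comp_n[component[r] - 1] += 1;
      }
      bool moved = false;
      for (int k = 0; k < n_components; ++k) {
        comp_sum[k] /= comp_n[k];
        if (comp_sum[k] != 0.0) moved = true;
      }
      if (moved) {
        for (int r = 0; r < n_regions; ++r) z[r] -= comp_sum[component[r] - 1];
        for (int c = 0; c < n_cells; ++c) {
          eta[c] -= comp_sum[component[region_index[c] - 1] - 1];
          cll[c] = cell_loglik(y, lgyf, c, eta[c], theta, lgamma_theta,
                               log_theta);
        }
      }

      // --- tau, conjugate gamma update ---
      if (!fix_tau) {
        double quad = 0.0;
        for (int e = 0; e < edges.nrow(); ++e) {
          const double d = z[edges(e, 0) - 1] - z[edges(e, 1) - 1];
          quad += d * d;
        }
        tau = R::rgamma(tau_shape + 0.5 * (n_regions - n_components),
                        1.0 / (tau_rate + 0.5 * quad));
      }
    }

    // --- burn-in adaptation toward 44% acceptance ---
    if (iter <= n_burn && iter % adapt_window == 0) {
      for (int j = 0; j < p; ++j) {
        sd_a[j] *= exp(clampd((acc_a[j] / adapt_window - target), -0.5, 0.5));
        acc_a[j] = 0.0;
      }
      if (!fix_theta) {
        sd_t *= exp(clampd((acc_t / adapt_window - target), -0.5, 0.5));
        acc_t = 0.0;
      }
      if (include_icar) {
        for (int r = 0; r < n_regions; ++r) {
          sd_z[r] *= exp(clampd((acc_z[r] / adapt_window - target), -0.5, 0.5));
          acc_z[r] = 0.0;
        }
      }
    }

    // --- retain draw ---
    if (iter > n_burn && (iter - n_burn) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) out_alpha(kept, j) = alpha[j];
      out_lt[kept] = log_theta;
      out_tau[kept] = include_icar ? tau : NA_REAL;
      double ll = 0.0;
      for (int c = 0; c < n_cells; ++c) ll += cll[c];
      out_ll[kept] = ll;
      if (include_icar)
        for (int r = 0; r < n_regions; ++r) out_z(kept, r) = z[r];
      ++kept;
    }
  }

  return List::create(
    _["alpha"] = out_alpha,
    _["log_theta"] = out_lt,
    _["tau"] = out_tau,
    _["z"] = out_z,
    _["log_lik"] = out_ll,
    _["accept"] = List::create(
      _["alpha"] = n_prop_a ? total_acc_a / n_prop_a : NA_REAL,
      _["log_theta"] = n_prop_t ? total_acc_t / n_prop_t : NA_REAL,
      _["z"] = n_prop_z ? total_acc_z / n_prop_z : NA_REAL));
}
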