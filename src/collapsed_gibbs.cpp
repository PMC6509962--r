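// Collapsed Gibbs sampler for the t-augmented Gaussian mixture.
//
// Component means/covariances and the mixture weights are integrated out
// analytically (normal-inverse-Wishart and Dirichlet conjugacy), as is the
// Beta-distributed outlier weight. Each sweep jointly resamples the class
// z_i and outlier indicator o_i of every unknown protein from the 2K-state
// full conditional; markers contribute fixed sufficient statistics and are
// never resampled. Randomness comes from R's RNG so chains are reproducible
// with set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log density of a multivariate t at x (location mu, scale S, df nu),
// with a ridge fallback should the scale fail to factorise
static double logdmvt(const vec& x, const vec& mu, mat S, double nu) {
  const double d = (double) x.n_elem;
  mat U;
  if (!chol(U, S)) {
    double md = mean(S.diag());
    double ridge = (md > 0.0 ? 1e-6 * md : 1e-6);
    for (int i = 0; i < 30 && !chol(U, S); ++i) {
      S.diag() += ridge;
      ridge *= 10.0;
    }
  }
  vec z = solve(trimatl(U.t()), x - mu);
  double q = dot(z, z);
  double ldet = 2.0 * sum(log(U.diag()));
  return lgamma(0.5 * (nu + d)) - lgamma(0.5 * nu)
    - 0.5 * d * std::log(nu * M_PI) - 0.5 * ldet
    - 0.5 * (nu + d) * std::log1p(q / nu);
}

// [[Rcpp::export(name = ".collapsed_gibbs_chain")]]
Rcpp::List collapsed_gibbs_chain(const arma::mat& X,
                                 const arma::uvec& unknown_idx, // 0-based rows
                                 const arma::ivec& init_alloc,  // 0-based, per unknown
                                 const arma::ivec& init_outlier,// 0/1, per unknown
                                 const arma::ivec& marker_class,// 0-based, -1 = unknown
                                 const arma::vec& mu0,
                                 double lambda0, double nu0,
                                 const arma::mat& S0,
                                 const arma::vec& beta0,
                                 double u, double v,
                                 const arma::vec& out_mu,
                                 const arma::mat& out_sigma,
                                 double out_df,
                                 int num_iter, int burnin, int thin) {
  const uword n = X.n_rows, D = X.n_cols, K = beta0.n_elem;
  const uword nU = unknown_idx.n_elem;
  const int T = (num_iter - burnin) / thin;

  // class state: Dirichlet counts over all proteins, Gaussian sufficient
  // statistics over non-outlier members only
  vec n_all(K, fill::zeros);
  vec m_gauss(K, fill::zeros);
  mat sum_gauss(D, K, fill::zeros);
  cube ss_gauss(D, D, K, fill::zeros);
  double n_out = 0.0, n_nonout = 0.0;

  ivec z(n), o(n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    if (marker_class[i] >= 0) z[i] = marker_class[i];
  }
  for (uword j = 0; j < nU; ++j) {
    z[unknown_idx[j]] = init_alloc[j];
    o[unknown_idx[j]] = init_outlier[j];
  }

  for (uword i = 0; i < n; ++i) {
    uword k = (uword) z[i];
    n_all[k] += 1.0;
    if (o[i] == 0) {
      m_gauss[k] += 1.0;
      sum_gauss.col(k) += X.row(i).t();
      ss_gauss.slice(k) += X.row(i).t() * X.row(i);
      n_nonout += 1.0;
    } else {
      n_out += 1.0;
    }
  }

  imat keep_z(T, nU), keep_o(T, nU);
  mat keep_pout(T, nU);
  cube keep_p(nU, K, T);

  const mat mu0_outer = lambda0 * (mu0 * mu0.t());
  vec logmass(2 * K);
  mat pclass(nU, K);
  vec pout(nU);

  Rcpp::RNGScope scope;

  for (int iter = 1; iter <= num_iter; ++iter) {
    for (uword j = 0; j < nU; ++j) {
      const uword i = unknown_idx[j];
      const vec xi = X.row(i).t();
      const uword zi = (uword) z[i];

      // remove protein i from the current state
      n_all[zi] -= 1.0;
      if (o[i] == 0) {
        m_gauss[zi] -= 1.0;
        sum_gauss.col(zi) -= xi;
        ss_gauss.slice(zi) -= xi * xi.t();
        n_nonout -= 1.0;
      } else {
        n_out -= 1.0;
      }

      const double log_t = logdmvt(xi, out_mu, out_sigma, out_df);
      for (uword k = 0; k < K; ++k) {
        const double m = m_gauss[k];
        const double lam_m = lambda0 + m;
        const double nu_m = nu0 + m;
        const vec mu_m = (lambda0 * mu0 + sum_gauss.col(k)) / lam_m;
        mat S_m = S0 + ss_gauss.slice(k) + mu0_outer
          - lam_m * (mu_m * mu_m.t());
        S_m = 0.5 * (S_m + S_m.t());
        const double df = nu_m - (double) D + 1.0;
        const mat scale = S_m * ((lam_m + 1.0) / (lam_m * df));
        const double pred = logdmvt(xi, mu_m, scale, df);
        const double lw = std::log(beta0[k] + n_all[k]);
        logmass[k]     = lw + std::log(v + n_nonout) + pred;
        logmass[K + k] = lw + std::log(u + n_out) + log_t;
      }

      const double mx = logmass.max();
      vec w = exp(logmass - mx);
      const double tot = sum(w);
      // per-sweep class probabilities marginal over the outlier indicator;
      // outlier probability is the mass of the o = 1 states
      double po = 0.0;
      for (uword k = 0; k < K; ++k) {
        pclass(j, k) = (w[k] + w[K + k]) / tot;
        po += w[K + k] / tot;
      }
      pout[j] = po;

      const double r = R::unif_rand() * tot;
      double acc = 0.0;
      uword state = 2 * K - 1;
      for (uword s = 0; s < 2 * K; ++s) {
        acc += w[s];
        if (r <= acc) { state = s; break; }
      }
      const uword k_new = state % K;
      const int o_new = state < K ? 0 : 1;

      z[i] = (int) k_new;
      o[i] = o_new;
      n_all[k_new] += 1.0;
      if (o_new == 0) {
        m_gauss[k_new] += 1.0;
        sum_gauss.col(k_new) += xi;
        ss_gauss.slice(k_new) += xi * xi.t();
        n_nonout += 1.0;
      } else {
        n_out += 1.0;
      }
    }

    if (iter > burnin && (iter - burnin) % thin == 0) {
      const int t = (iter - burnin) / thin - 1;
      for (uword j = 0; j < nU; ++j) {
        keep_z(t, j) = z[unknown_idx[j]] + 1;  // back to 1-based
        keep_o(t, j) = o[unknown_idx[j]];
        keep_pout(t, j) = pout[j];
      }
      keep_p.slice(t) = pclass;
    }
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("alloc") = keep_z,
    Rcpp::Named("outlier") = keep_o,
    Rcpp::Named("outlier_prob") = keep_pout,
    Rcpp::Named("prob") = keep_p);
}
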