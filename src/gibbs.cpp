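// Blocked Gibbs sampler for the multi-response (phylogenetic) mixed model
//
//   y_twi = beta_t + u_{s:tw} + u_{p:tw} + e_twi
//
// with u_s ~ N(0, V_s (x) I_S), u_p ~ N(0, V_p (x) A) and independent
// per-trait residual variances. Location effects are drawn jointly from
// their Gaussian full conditional (mixed-model equations), covariance
// matrices from inverse-Wishart full conditionals (optionally with
// parameter-expanded working scales), residual variances from scaled
// inverse-chi-square conditionals. All randomness goes through the R RNG,
// so set.seed() in R makes runs reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double r_norm() { return R::rnorm(0.0, 1.0); }

// Inverse-Wishart draw, density |V|^{-(nu+d+1)/2} exp(-tr(S V^{-1})/2):
// V^{-1} ~ Wishart(nu, S^{-1}) via the Bartlett decomposition.
static mat riwish(double nu, const mat& S) {
  const uword d = S.n_rows;
  mat Sinv;
  if (!inv_sympd(Sinv, symmatu(S))) {
    Sinv = pinv(symmatu(S) + 1e-10 * eye(d, d));
  }
  mat L = chol(symmatu(Sinv), "lower");
  mat A(d, d, fill::zeros);
  for (uword i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = r_norm();
  }
  mat X = L * A;
  mat W = X * X.t();
  mat V;
  if (!inv_sympd(V, symmatu(W))) {
    V = pinv(symmatu(W) + 1e-10 * eye(d, d));
  }
  return symmatu(V);
}

static mat safe_inv_sympd(const mat& V) {
  mat out;
  mat Vs = symmatu(V);
  if (inv_sympd(out, Vs)) return out;
  double ridge = 1e-10 * (1.0 + std::abs(Vs.diag().max()));
  for (int k = 0; k < 8 && !inv_sympd(out, Vs + ridge * eye(size(Vs))); ++k) {
    ridge *= 100.0;
  }
  return out;
}

static bool is_pd(const mat& V) {
  mat R;
  return chol(R, symmatu(V));
}

// [[Rcpp::export]]
Rcpp::List gibbs_multiresponse(
    const arma::vec& y,
    const arma::uvec& trait,   // 0-based, length n
    const arma::uvec& strain,  // 0-based, length n
    int n_traits, int n_strains,
    bool use_strain, bool use_phylo,
    const arma::mat& Ainv,     // S x S (ignored unless use_phylo)
    int prior,                 // 0 = parameter-expanded, 1 = inv-Wishart, 2 = flat
    double nu0, const arma::mat& S0,       // IW hyperparameters (prior 1)
    double nu_px, const arma::mat& S0_px,  // working-scale IW (prior 0)
    double alpha_var,                      // working-parameter prior variance
    double nu_e, double s2_e,              // residual scaled-inv-chi2 prior
    int n_iter, int burn_in, int thin,
    const arma::mat& Vs_init, const arma::mat& Vp_init) {

  const uword n = y.n_elem;
  const uword T = (uword)n_traits;
  const uword S = (uword)n_strains;
  const uword off_s = T;
  const uword off_p = T + (use_strain ? T * S : 0);
  const uword P = T + (use_strain ? T * S : 0) + (use_phylo ? T * S : 0);

  // dense design: trait intercepts + per-component (trait, strain) indicators
  mat W(n, P, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    W(i, trait(i)) = 1.0;
    if (use_strain) W(i, off_s + trait(i) * S + strain(i)) = 1.0;
    if (use_phylo)  W(i, off_p + trait(i) * S + strain(i)) = 1.0;
  }

  // per-trait normal-equation pieces (residual variance differs by trait)
  std::vector<mat> Ct(T);
  std::vector<vec> bt(T);
  std::vector<uvec> rows_t(T);
  vec n_t(T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    rows_t[t] = find(trait == t);
    n_t(t) = (double)rows_t[t].n_elem;
    mat Wt = W.rows(rows_t[t]);
    Ct[t] = Wt.t() * Wt;
    bt[t] = Wt.t() * y.elem(rows_t[t]);
  }

  // starting values
  vec sigma2(T);
  for (uword t = 0; t < T; ++t) {
    double v = n_t(t) > 1 ? var(y.elem(rows_t[t])) : 1.0;
    sigma2(t) = std::max(v / 2.0, 1e-3);
  }
  mat Vs = Vs_init.n_rows == T ? Vs_init : mat(diagmat(sigma2));
  mat Vp = Vp_init.n_rows == T ? Vp_init : mat(diagmat(sigma2));
  mat Lam_s(T, T, fill::eye), Lam_p(T, T, fill::eye);
  vec theta(P, fill::zeros);

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  mat out_beta(n_keep, T);
  mat out_Vs(use_strain ? n_keep : 0, T * T);
  mat out_Vp(use_phylo ? n_keep : 0, T * T);
  mat out_sigma2(n_keep, T);
  int kept = 0, npd_rejects = 0;

  // gather U (S x T) from theta for a component at column offset `off`
  auto gather_U = [&](uword off) {
    mat U(S, T);
    for (uword t = 0; t < T; ++t) U.col(t) = theta.subvec(off + t * S, off + t * S + S - 1);
    return U;
  };
  auto scatter_U = [&](uword off, const mat& U) {
    for (uword t = 0; t < T; ++t) theta.subvec(off + t * S, off + t * S + S - 1) = U.col(t);
  };

  // draw one covariance matrix; reject (resample) non-PD draws
  auto draw_cov = [&](double df, const mat& scale) {
    mat V;
    for (int k = 0; k < 25; ++k) {
      V = riwish(df, scale);
      if (is_pd(V)) return V;
      ++npd_rejects;
    }
    V = symmatu(V + 1e-8 * eye(T, T));
    return V;
  };

  for (int it = 0; it < n_iter; ++it) {
    if (it % 512 == 0) Rcpp::checkUserInterrupt();

    // ---- (i) joint Gaussian draw of fixed + random location effects ----
    mat Prec(P, P, fill::zeros);
    vec rhs(P, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      Prec += Ct[t] / sigma2(t);
      rhs += bt[t] / sigma2(t);
    }
    for (uword t = 0; t < T; ++t) Prec(t, t) += 1e-10; // vague N(0, 1e10) on beta
    if (use_strain) {
      mat Vsi = safe_inv_sympd(Vs);
      for (uword t1 = 0; t1 < T; ++t1)
        for (uword t2 = 0; t2 < T; ++t2)
          for (uword s = 0; s < S; ++s)
            Prec(off_s + t1 * S + s, off_s + t2 * S + s) += Vsi(t1, t2);
    }
    if (use_phylo) {
      mat Vpi = safe_inv_sympd(Vp);
      for (uword t1 = 0; t1 < T; ++t1)
        for (uword t2 = 0; t2 < T; ++t2)
          Prec.submat(off_p + t1 * S, off_p + t2 * S,
                      off_p + t1 * S + S - 1, off_p + t2 * S + S - 1)
            += Vpi(t1, t2) * Ainv;
    }
    mat Rc;
    if (!chol(Rc, symmatu(Prec))) {
      double ridge = 1e-8 * (1.0 + std::abs(Prec.diag().max()));
      bool ok = false;
      for (int k = 0; k < 10 && !ok; ++k, ridge *= 100.0) {
        ok = chol(Rc, symmatu(Prec) + ridge * eye(P, P));
      }
      if (!ok) Rcpp::stop("location-effect precision matrix is not positive definite");
    }
    vec mu = solve(trimatu(Rc), solve(trimatl(Rc.t()), rhs));
    vec z(P);
    for (uword j = 0; j < P; ++j) z(j) = r_norm();
    theta = mu + solve(trimatu(Rc), z);

    // ---- (ii)/(iii) covariance updates ----
    // Parameter expansion uses a full working loadings matrix Lam:
    // u(s,.) = Lam * eta(s,.), eta ~ N(0, Psi (x) Q), V = Lam Psi Lam'.
    // Row t of Lam is redrawn from a Gaussian regression of the trait-t
    // data on the eta columns, so the data (not the prior reproduction of
    // u' Q^-1 u) drive the cross-trait structure; this is what rescues
    // mixing when a component is weakly identified.
    auto update_component = [&](uword off, const mat* Qinv, mat& V,
                                mat& Lam, uword off_other, bool has_other) {
      mat U = gather_U(off);
      if (prior == 0) {
        mat Lam_inv;
        if (!inv(Lam_inv, Lam)) {
          Lam_inv = pinv(Lam + 1e-10 * eye(T, T));
        }
        mat eta = U * Lam_inv.t();            // U = eta * Lam'
        mat quad = Qinv ? mat(eta.t() * (*Qinv) * eta) : mat(eta.t() * eta);
        mat Psi = draw_cov(nu_px + (double)S, S0_px + quad);
        vec fit_other(n);
        for (uword i = 0; i < n; ++i) {
          fit_other(i) = theta(trait(i));
          if (has_other)
            fit_other(i) += theta(off_other + trait(i) * S + strain(i));
        }
        // per-trait rows: y_i - fit_other = Lam.row(t) * eta(s_i,.) + e
        for (uword t = 0; t < T; ++t) {
          mat G(rows_t[t].n_elem, T);
          vec r(rows_t[t].n_elem);
          for (uword k = 0; k < rows_t[t].n_elem; ++k) {
            uword i = rows_t[t](k);
            G.row(k) = eta.row(strain(i));
            r(k) = y(i) - fit_other(i);
          }
          mat prec = G.t() * G / sigma2(t) + eye(T, T) / alpha_var;
          vec b = G.t() * r / sigma2(t);
          mat Rl;
          if (!chol(Rl, symmatu(prec))) {
            double ridge = 1e-8 * (1.0 + std::abs(prec.diag().max()));
            bool ok = false;
            for (int k = 0; k < 10 && !ok; ++k, ridge *= 100.0) {
              ok = chol(Rl, symmatu(prec) + ridge * eye(T, T));
            }
            if (!ok) Rcpp::stop("working-scale precision is not positive definite");
          }
          vec mlam = solve(trimatu(Rl), solve(trimatl(Rl.t()), b));
          vec zl(T);
          for (uword j = 0; j < T; ++j) zl(j) = r_norm();
          Lam.row(t) = (mlam + solve(trimatu(Rl), zl)).t();
        }
        U = eta * Lam.t();
        scatter_U(off, U);
        V = symmatu(Lam * Psi * Lam.t());
        if (!is_pd(V)) V += 1e-10 * eye(T, T);
      } else {
        mat quad = Qinv ? mat(U.t() * (*Qinv) * U) : mat(U.t() * U);
        double df = (prior == 2 ? -(double)(T + 1) : nu0) + (double)S;
        V = draw_cov(df, S0 + quad);
      }
    };
    if (use_strain) {
      update_component(off_s, nullptr, Vs, Lam_s, off_p, use_phylo);
    }
    if (use_phylo) {
      update_component(off_p, &Ainv, Vp, Lam_p, off_s, use_strain);
    }

    // ---- (iv) residual variances, scaled inverse-chi-square ----
    vec resid = y - W * theta;
    for (uword t = 0; t < T; ++t) {
      double ss = nu_e * s2_e + accu(square(resid.elem(rows_t[t])));
      sigma2(t) = ss / R::rchisq(nu_e + n_t(t));
    }

    // ---- record ----
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (uword t = 0; t < T; ++t) out_beta(kept, t) = theta(t);
      if (use_strain) out_Vs.row(kept) = vectorise(Vs).t();
      if (use_phylo) out_Vp.row(kept) = vectorise(Vp).t();
      out_sigma2.row(kept) = sigma2.t();
      ++kept;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = out_beta.rows(0, kept - 1),
    Rcpp::Named("V_s") = use_strain ? out_Vs.rows(0, kept - 1) : mat(0, T * T),
    Rcpp::Named("V_p") = use_phylo ? out_Vp.rows(0, kept - 1) : mat(0, T * T),
    Rcpp::Named("sigma2") = out_sigma2.rows(0, kept - 1),
    Rcpp::Named("npd_rejects") = npd_rejects);
}
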