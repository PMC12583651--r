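// Core samplers for Bayesian Gaussian copula graphical models:
//  - direct G-Wishart sampler (Wishart draw + maximum-entropy completion)
//  - single-edge trans-dimensional Metropolis-Hastings with an exchange step,
//    so no G-Wishart normalizing constants are ever evaluated
//  - extended-rank-likelihood Gibbs sweep for discrete latent columns
// All randomness goes through R's RNG so set.seed() governs everything.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Wishart_p(df, Scale) via Bartlett decomposition (R RNG); L = chol(Scale)
// lower triangular, cached by callers that reuse the same scale.
static arma::mat rwish_chol(double df, const arma::mat& L) {
  const int p = L.n_rows;
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::mat safe_inv_sympd(const arma::mat& M) {
  arma::mat out;
  if (arma::inv_sympd(out, M)) return out;
  // bounded jitter retry (numerical floor; see sampler design notes)
  arma::mat Mj = M;
  double jit = 1e-10 * (1.0 + arma::norm(M, "inf"));
  for (int t = 0; t < 6; ++t) {
    Mj.diag() += jit;
    if (arma::inv_sympd(out, Mj)) return out;
    jit *= 100.0;
  }
  stop("matrix inversion failed: input not positive definite");
}

// ---------------------------------------------------------------------------
// Direct sampler for GW(delta, D) restricted to graph `adj`
// (density |K|^((delta-2)/2) exp(-tr(D K)/2)): draw from the complete-graph
// Wishart, then complete Sigma so that K = W^{-1} carries exact zeros on
// non-edges (Lenkoski-style block completion, iterated to convergence).
static arma::mat rgwish_core(const arma::umat& adj, double delta,
                             const arma::mat& cholDinv, double tol,
                             int maxit) {
  const int p = cholDinv.n_rows;
  arma::mat K = rwish_chol(delta + p - 1.0, cholDinv);
  if (arma::all(arma::vectorise(adj) == 0) || p == 1) {
    // empty graph: free elements are the diagonal only
    arma::mat Kout(p, p, arma::fill::zeros);
    arma::mat Sigma = safe_inv_sympd(K);
    for (int j = 0; j < p; ++j) Kout(j, j) = 1.0 / Sigma(j, j);
    return Kout;
  }
  arma::mat Sigma = safe_inv_sympd(K);
  arma::mat W = Sigma;
  std::vector<arma::uvec> nb(p);
  bool complete = true;
  for (int j = 0; j < p; ++j) {
    nb[j] = arma::find(adj.col(j) == 1);
    if ((int)nb[j].n_elem < p - 1) complete = false;
  }
  if (!complete) {
    const double scl = 1.0 + arma::norm(Sigma, "inf");
    for (int it = 0; it < maxit; ++it) {
      double delta_w = 0.0;
      for (int j = 0; j < p; ++j) {
        const arma::uvec& N = nb[j];
        arma::uvec jj(1); jj(0) = j;
        arma::vec wnew(p, arma::fill::zeros);
        if (N.n_elem > 0) {
          arma::vec beta = arma::solve(W.submat(N, N), Sigma.submat(N, jj),
                                       arma::solve_opts::likely_sympd);
          wnew = W.cols(N) * beta;
        }
        for (int r = 0; r < p; ++r) {
          if (r == j) continue;
          double d = std::abs(W(r, j) - wnew(r));
          if (d > delta_w) delta_w = d;
          W(r, j) = wnew(r);
          W(j, r) = wnew(r);
        }
      }
      if (delta_w < tol * scl) break;
    }
  }
  arma::mat Kout = safe_inv_sympd(W);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j && adj(i, j) == 0) Kout(i, j) = 0.0;
  return 0.5 * (Kout + Kout.t());
}

static arma::mat chol_lower_inv(const arma::mat& D) {
  return arma::chol(safe_inv_sympd(D), "lower");
}

// [[Rcpp::export]]
arma::mat rgwish_cpp(const arma::umat& adj, double delta, const arma::mat& D,
                     double tol, int maxit) {
  return rgwish_core(adj, delta, chol_lower_inv(D), tol, maxit);
}

// ---------------------------------------------------------------------------
// log of the ratio of conditional integrals I1/I0 for edge (i,j) under
// GW(delta, Dmat) parameters, where I1 integrates the free pair (k_ij, gamma)
// and I0 integrates gamma alone (k_ij pinned at 0), conditioning on the rest
// of K. Column j is the focus column; gamma is the Schur complement of k_jj.
// Closed form: I1/I0 = sqrt(2*pi/a) * exp(b^2/(2a)) with
//   a = D_jj * C_ii,  b = D_jj * sum_{l != i} C_il beta_l + D_ij,
//   C = inv(K[-j,-j]), beta = K[-j, j].
static double log_cond_ratio(const arma::mat& K, int i, int j,
                             const arma::mat& Dmat) {
  const int p = K.n_rows;
  arma::uvec idx(p - 1);
  int pos_i = -1, t = 0;
  for (int r = 0; r < p; ++r) {
    if (r == j) continue;
    if (r == i) pos_i = t;
    idx(t++) = r;
  }
  arma::uvec jj(1); jj(0) = j;
  arma::mat C = safe_inv_sympd(K.submat(idx, idx));
  arma::vec beta = K.submat(idx, jj);
  const double d = Dmat(j, j);
  double s = arma::dot(C.row(pos_i).t(), beta) - C(pos_i, pos_i) * beta(pos_i);
  const double a = d * C(pos_i, pos_i);
  const double b = d * s + Dmat(i, j);
  return 0.5 * std::log(2.0 * M_PI / a) + b * b / (2.0 * a);
}

// [[Rcpp::export]]
double log_cond_ratio_cpp(const arma::mat& K, int i0, int j0,
                          const arma::mat& Dmat) {
  return log_cond_ratio(K, i0, j0, Dmat);
}

// ---------------------------------------------------------------------------
// One truncated-normal draw on (lo, hi) with mean mu, sd sigma.
static double rtruncnorm1(double mu, double sigma, double lo, double hi) {
  double a = (lo == -INF) ? -INF : (lo - mu) / sigma;
  double b = (hi ==  INF) ?  INF : (hi - mu) / sigma;
  double pa = (a == -INF) ? 0.0 : R::pnorm(a, 0.0, 1.0, 1, 0);
  double pb = (b ==  INF) ? 1.0 : R::pnorm(b, 0.0, 1.0, 1, 0);
  double z;
  if (pb - pa > 1e-13) {
    double u = pa + R::unif_rand() * (pb - pa);
    z = R::qnorm(u, 0.0, 1.0, 1, 0);
  } else if (a != -INF && b != INF) {
    z = a + R::unif_rand() * (b - a);      // sliver between finite bounds
  } else if (b == INF) {
    z = a + R::exp_rand() / std::max(a, 1.0);   // far upper tail
  } else {
    z = b - R::exp_rand() / std::max(-b, 1.0);  // far lower tail
  }
  if (a != -INF && z <= a) z = a + 1e-10;
  if (b !=  INF && z >= b) z = b - 1e-10;
  return mu + sigma * z;
}

// Per-column bookkeeping for the extended-rank-likelihood sweep.
struct DiscCol {
  int zcol;                            // column index into Z
  std::vector<std::vector<int>> rows;  // row indices grouped by observed level
};

static std::vector<DiscCol> build_disc(const arma::imat& Ydisc,
                                       const arma::uvec& disc_idx) {
  std::vector<DiscCol> out;
  const int n = Ydisc.n_rows;
  for (unsigned c = 0; c < disc_idx.n_elem; ++c) {
    DiscCol dc;
    dc.zcol = disc_idx(c);
    std::map<int, std::vector<int>> groups;
    for (int r = 0; r < n; ++r) groups[Ydisc(r, c)].push_back(r);
    for (auto& kv : groups) dc.rows.push_back(kv.second);
    out.push_back(dc);
  }
  return out;
}

// Exact systematic-scan Gibbs sweep over the discrete columns (fixed
// column-major then row-major order). Levels are processed in increasing
// order: the lower truncation is the running maximum of already-updated
// lower levels, the upper truncation is the suffix minimum of the
// not-yet-updated higher levels. Ties impose no mutual constraint.
static void copula_sweep(arma::mat& Z, const std::vector<DiscCol>& disc,
                         const arma::mat& K) {
  const int n = Z.n_rows;
  if (n == 0) return;
  for (const DiscCol& dc : disc) {
    const int j = dc.zcol;
    const double kjj = K(j, j);
    const double sigma = 1.0 / std::sqrt(kjj);
    arma::vec m = Z * K.col(j);  // row-wise inner products with column j of K
    const size_t L = dc.rows.size();
    std::vector<double> sufmin(L + 1, INF);
    for (int l = (int)L - 1; l >= 0; --l) {
      double mn = INF;
      for (int r : dc.rows[l]) mn = std::min(mn, Z(r, j));
      sufmin[l] = std::min(sufmin[l + 1], mn);
    }
    double runmax = -INF;
    for (size_t l = 0; l < L; ++l) {
      const double hi = sufmin[l + 1];
      double newmax = -INF;
      for (int r : dc.rows[l]) {
        const double mu = -(m(r) - kjj * Z(r, j)) / kjj;
        const double z = rtruncnorm1(mu, sigma, runmax, hi);
        Z(r, j) = z;
        newmax = std::max(newmax, z);
      }
      runmax = std::max(runmax, newmax);
    }
  }
}

// [[Rcpp::export]]
arma::mat copula_sweep_cpp(arma::mat Z, const arma::imat& Ydisc,
                           const arma::uvec& disc_idx, const arma::mat& K) {
  std::vector<DiscCol> disc = build_disc(Ydisc, disc_idx);
  copula_sweep(Z, disc, K);
  return Z;
}

// ---------------------------------------------------------------------------
// Full chain. Each iteration: (a) discrete-latent Gibbs sweep under current K,
// (b) one single-edge exchange MH update of G, (c) K ~ GW(delta*, D*) | G.
// [[Rcpp::export]]
List gcgm_mcmc_cpp(arma::mat Z, const arma::imat& Ydisc,
                   const arma::uvec& disc_idx, arma::umat adj,
                   double delta, const arma::mat& Dprior, double gprior,
                   int iterations, int burnin, int thin,
                   double tol, int maxit) {
  const int p = Dprior.n_rows;
  const int n = Z.n_rows;
  const int M = p * (p - 1) / 2;
  const double deltastar = delta + n;
  const bool have_disc = (disc_idx.n_elem > 0 && n > 0);
  std::vector<DiscCol> disc =
      have_disc ? build_disc(Ydisc, disc_idx) : std::vector<DiscCol>();

  // pair index table (i < j), column-major over the upper triangle
  arma::umat pairs(2, M);
  { int t = 0;
    for (int j = 1; j < p; ++j)
      for (int i = 0; i < j; ++i) { pairs(0, t) = i; pairs(1, t) = j; ++t; } }

  arma::mat S(p, p, arma::fill::zeros);
  if (n > 0) S = Z.t() * Z;
  arma::mat Dstar = Dprior + S;

  const arma::mat cholDinv_prior = chol_lower_inv(Dprior);
  arma::mat cholDinv_star = chol_lower_inv(Dstar);

  arma::mat K = rgwish_core(adj, deltastar, cholDinv_star, tol, maxit);

  const int kept = iterations - burnin;
  const int nstored = kept / thin;
  arma::umat adj_samples(M, nstored, arma::fill::zeros);
  arma::mat partial_samples(M, nstored, arma::fill::zeros);
  arma::ivec edge_count(nstored, arma::fill::zeros);
  arma::mat freq(p, p, arma::fill::zeros);   // all post-burn-in iterations
  arma::mat half1(p, p, arma::fill::zeros);
  arma::mat half2(p, p, arma::fill::zeros);
  long accepted = 0;
  int stored = 0;

  const double lodds = std::log(gprior) - std::log1p(-gprior);

  for (int iter = 0; iter < iterations; ++iter) {
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
    // (a) copula layer; only the discrete rows/columns of S = Z'Z change
    if (have_disc) {
      copula_sweep(Z, disc, K);
      arma::mat Sd = Z.t() * Z.cols(disc_idx);
      for (unsigned c = 0; c < disc_idx.n_elem; ++c) {
        S.col(disc_idx(c)) = Sd.col(c);
        S.row(disc_idx(c)) = Sd.col(c).t();
      }
      Dstar = Dprior + S;
      cholDinv_star = chol_lower_inv(Dstar);
    }
    // (b) single-edge exchange MH
    {
      int e = (int)std::floor(R::unif_rand() * M);
      if (e == M) e = M - 1;
      const int i = pairs(0, e), j = pairs(1, e);
      const bool adding = (adj(i, j) == 0);
      arma::umat adj_prop = adj;
      adj_prop(i, j) = adj_prop(j, i) = adding ? 1 : 0;
      arma::mat K0 = rgwish_core(adj_prop, delta, cholDinv_prior, tol, maxit);
      const double lr_post = log_cond_ratio(K, i, j, Dstar);
      const double lr_aux = log_cond_ratio(K0, i, j, Dprior);
      const double la = adding ? (lodds + lr_post - lr_aux)
                               : (-lodds - lr_post + lr_aux);
      if (la >= 0.0 || std::log(R::unif_rand()) < la) {
        adj = adj_prop;
        ++accepted;
      }
    }
    // (c) precision refresh from the conditional posterior
    K = rgwish_core(adj, deltastar, cholDinv_star, tol, maxit);

    if (iter >= burnin) {
      const int post = iter - burnin;
      arma::mat adj_d = arma::conv_to<arma::mat>::from(adj);
      freq += adj_d;
      if (post < kept / 2) half1 += adj_d; else half2 += adj_d;
      if (post % thin == 0 && stored < nstored) {
        int ec = 0;
        for (int e = 0; e < M; ++e) {
          const int i = pairs(0, e), j = pairs(1, e);
          adj_samples(e, stored) = adj(i, j);
          if (adj(i, j) == 1) {
            partial_samples(e, stored) = -K(i, j) / std::sqrt(K(i, i) * K(j, j));
            ++ec;
          }
        }
        edge_count(stored) = ec;
        ++stored;
      }
    }
  }
  freq /= std::max(kept, 1);
  half1 /= std::max(kept / 2, 1);
  half2 /= std::max(kept - kept / 2, 1);

  return List::create(
      _["adj_samples"] = adj_samples, _["partial_samples"] = partial_samples,
      _["edge_count"] = edge_count, _["pairs"] = pairs,
      _["edge_freq"] = freq, _["half1"] = half1, _["half2"] = half2,
      _["accept_rate"] = (double)accepted / iterations,
      _["nstored"] = stored);
}
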