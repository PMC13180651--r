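// Newton-Raphson core for weighted multinomial logistic regression with an
// optional L2 penalty on non-intercept coefficients, in grouped
// (sufficient-statistic) form: rows of Xu are the unique covariate patterns
// and Y holds the weighted destination counts per pattern, so the cost per
// iteration is driven by the number of patterns, not the number of
// observations. Reference-category coefficients are fixed at zero; columns
// of B correspond to the non-reference categories in ascending order.
// Step-halving enforces a monotone penalized log-likelihood trace.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double penalized_ll(const mat& Xu, const mat& Y, const vec& Nc,
                           const ivec& nonref, int ref, double lambda,
                           const mat& B, mat& P, double& ll_unpen) {
  const uword C = Xu.n_rows;
  const uword m = B.n_cols;
  mat eta = Xu * B;                      // C x m
  vec mx = max(join_rows(eta, zeros<vec>(C)), 1);
  mat E = exp(eta.each_col() - mx);
  vec denom = exp(-mx) + sum(E, 1);
  P = E.each_col() / denom;              // non-reference probabilities
  double ll = 0.0;
  for (uword c = 0; c < C; ++c) {
    double s = 0.0;
    for (uword j = 0; j < m; ++j) s += Y(c, nonref(j) - 1) * eta(c, j);
    ll += s - Nc(c) * (mx(c) + std::log(denom(c)));
  }
  ll_unpen = ll;
  double pen = 0.0;
  for (uword j = 0; j < m; ++j)
    for (uword k = 1; k < B.n_rows; ++k) pen += B(k, j) * B(k, j);
  return ll - 0.5 * lambda * pen;
}

static void fill_hessian(const mat& Xu, const vec& Nc, const mat& P,
                         double lambda, uword p, uword m, mat& H) {
  for (uword j = 0; j < m; ++j) {
    for (uword k = j; k < m; ++k) {
      vec wjk = Nc % P.col(j) % ((j == k ? 1.0 : 0.0) - P.col(k));
      mat blk = Xu.t() * (Xu.each_col() % wjk);
      H.submat(j * p, k * p, j * p + p - 1, k * p + p - 1) = blk;
      if (k > j)
        H.submat(k * p, j * p, k * p + p - 1, j * p + p - 1) = blk.t();
    }
  }
  for (uword j = 0; j < m; ++j)
    for (uword k = 1; k < p; ++k) H(j * p + k, j * p + k) += lambda;
  H.diag() += 1e-12;
}

// [[Rcpp::export]]
Rcpp::List newton_multinom(const arma::mat& Xu, const arma::mat& Y,
                           const int ref, const double lambda,
                           const int max_iter, const double tol,
                           const arma::mat& Bstart, const bool compute_vcov) {
  const uword p = Xu.n_cols;
  const int K = Y.n_cols;
  ivec nonref(K - 1);
  {
    int idx = 0;
    for (int k = 1; k <= K; ++k) if (k != ref) nonref(idx++) = k;
  }
  const uword m = K - 1;
  vec Nc = sum(Y, 1);
  mat B = Bstart;
  if (B.n_rows != p || B.n_cols != m) B = zeros<mat>(p, m);

  mat P;
  double ll_unpen = 0.0;
  double cur = penalized_ll(Xu, Y, Nc, nonref, ref, lambda, B, P, ll_unpen);
  std::vector<double> trace;
  trace.push_back(cur);
  bool converged = false;
  int iter = 0;
  mat H(p * m, p * m);

  while (iter < max_iter) {
    ++iter;
    vec g(p * m);
    for (uword j = 0; j < m; ++j) {
      vec r = Y.col(nonref(j) - 1) - Nc % P.col(j);
      g.subvec(j * p, j * p + p - 1) = Xu.t() * r;
      for (uword k = 1; k < p; ++k)
        g(j * p + k) -= lambda * B(k, j);
    }
    fill_hessian(Xu, Nc, P, lambda, p, m, H);
    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      H.diag() += 1e-6;
      step = solve(H, g);
    }
    double alpha = 1.0;
    mat Bn, Pn;
    double nxt = 0.0, llu = 0.0;
    while (true) {
      Bn = B + alpha * reshape(step, p, m);
      nxt = penalized_ll(Xu, Y, Nc, nonref, ref, lambda, Bn, Pn, llu);
      if (nxt >= cur - 1e-12 || alpha < 1e-8) break;
      alpha *= 0.5;
    }
    if (nxt < cur) {  // step-halving exhausted: no ascent direction left
      converged = true;
      trace.push_back(cur);
      break;
    }
    double rel = std::fabs(nxt - cur) / (std::fabs(cur) + 1e-300);
    B = Bn;
    P = Pn;
    cur = nxt;
    ll_unpen = llu;
    trace.push_back(cur);
    if (rel < tol) { converged = true; break; }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("coef") = B,
      Rcpp::Named("nonref") = nonref,
      Rcpp::Named("ref") = ref,
      Rcpp::Named("loglik") = ll_unpen,
      Rcpp::Named("loglik_trace") = trace,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("lambda") = lambda,
      Rcpp::Named("n") = (int)Xu.n_rows,
      Rcpp::Named("sum_weights") = accu(Y));
  if (compute_vcov) {
    fill_hessian(Xu, Nc, P, lambda, p, m, H);
    mat V;
    if (!inv_sympd(V, H)) {
      Rcpp::warning("singular information matrix; vcov from a ridged inverse");
      V = inv(H + 1e-8 * eye(p * m, p * m));
    }
    out["vcov"] = V;
  } else {
    out["vcov"] = R_NilValue;
  }
  return out;
}
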