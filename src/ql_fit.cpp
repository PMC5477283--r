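// Estimation core for the quasi-linear logistic model.
//
// Parameter vector theta = (alpha_1..alpha_K, beta_1..beta_p) with beta in
// marker order; cluster membership is passed as a 0-based index per marker.
// Both solvers work on the (already standardized) design passed from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Per-sample cluster scores L (n x K), softmax weights S, quasi-linear
// score q and fitted probability pi.
static void ql_forward(const mat& X, const uvec& cl, const vec& alpha,
                       const vec& beta, mat& L, mat& S, vec& q, vec& pi) {
  const uword n = X.n_rows, K = alpha.n_elem;
  L.set_size(n, K);
  L.each_row() = alpha.t();
  for (uword j = 0; j < X.n_cols; ++j) {
    if (beta[j] != 0.0) L.col(cl[j]) += beta[j] * X.col(j);
  }
  vec m = max(L, 1);
  mat E = exp(L.each_col() - m);
  vec se = sum(E, 1);
  q = m + log(se);
  S = E.each_col() / se;
  pi = 1.0 / (1.0 + exp(-q));
}

// Bernoulli log-likelihood sum(y*q - log(1+exp(q))), stable for large |q|.
static double bernoulli_ll(const vec& y, const vec& q) {
  vec soft = max(q, zeros<vec>(q.n_elem)) + log1p(exp(-abs(q)));
  return dot(y, q) - accu(soft);
}

// Design matrix of the working GLM: columns (S_k, S_{cl(j)} x_j).
static void build_W(const mat& X, const uvec& cl, const mat& S, mat& W) {
  const uword n = X.n_rows, p = X.n_cols, K = S.n_cols;
  W.set_size(n, K + p);
  W.cols(0, K - 1) = S;
  for (uword j = 0; j < p; ++j) W.col(K + j) = S.col(cl[j]) % X.col(j);
}

// Fisher scoring for the (optionally ridge-penalized) quasi-linear logistic
// likelihood. rdiag holds the ridge weights per theta coordinate (zeros for
// the unpenalized fit). Returns the iterate trace of the penalized
// log-likelihood; step-halving keeps the trace nondecreasing.
// [[Rcpp::export]]
Rcpp::List cpp_fit_fisher(const arma::mat& X, const arma::vec& y,
                          const arma::uvec& cl, const arma::vec& alpha0,
                          const arma::vec& beta0, const arma::vec& rdiag,
                          double tol, int max_iter) {
  const uword K = alpha0.n_elem, p = X.n_cols;
  vec theta = join_cols(alpha0, beta0);
  mat L, S, W;
  vec q, pi;
  std::vector<double> trace;
  bool converged = false, singular = false;
  ql_forward(X, cl, theta.head(K), theta.tail(p), L, S, q, pi);
  double obj = bernoulli_ll(y, q) - 0.5 * dot(rdiag, square(theta));
  trace.push_back(obj);
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    build_W(X, cl, S, W);
    vec v = clamp(pi % (1.0 - pi), 1e-10, 0.25);
    vec grad = W.t() * (y - pi) - rdiag % theta;
    mat info = W.t() * (W.each_col() % v);
    info.diag() += rdiag;
    vec delta;
    bool ok = solve(delta, info, grad, solve_opts::no_approx);
    if ((!ok || !delta.is_finite()) && it == 0) {
      // the symmetric start (beta = 0, equal alpha) makes the intercept
      // columns of W collinear; take the minimum-norm Fisher step once
      mat pinv_info;
      ok = pinv(pinv_info, info);
      if (ok) { delta = pinv_info * grad; ok = delta.is_finite(); }
    }
    if (!ok || !delta.is_finite()) { singular = true; break; }
    // step halving: Fisher steps are not globally ascent-safe here
    double step = 1.0, obj_new = -datum::inf;
    vec theta_new;
    for (int h = 0; h < 20; ++h) {
      theta_new = theta + step * delta;
      ql_forward(X, cl, theta_new.head(K), theta_new.tail(p), L, S, q, pi);
      obj_new = bernoulli_ll(y, q) - 0.5 * dot(rdiag, square(theta_new));
      if (obj_new >= obj - 1e-10) break;
      step *= 0.5;
    }
    if (obj_new < obj - 1e-10) { // no ascent step found: accept no move
      ql_forward(X, cl, theta.head(K), theta.tail(p), L, S, q, pi);
      converged = true;
      break;
    }
    double rel = std::abs(obj_new - obj) / (std::abs(obj) + 1e-10);
    theta = theta_new;
    obj = obj_new;
    trace.push_back(obj);
    if (rel < tol) { converged = true; ++it; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("alpha") = theta.head(K), Rcpp::Named("beta") = theta.tail(p),
      Rcpp::Named("trace") = trace, Rcpp::Named("converged") = converged,
      Rcpp::Named("singular") = singular, Rcpp::Named("n_iter") = it);
}

// Soft-thresholded ascent direction g for the L1-penalized likelihood.
// Intercept coordinates carry the raw gradient; a beta coordinate at zero
// moves only if its gradient exceeds its penalty.
static vec lasso_direction(const vec& grad, const vec& theta, const vec& lam,
                           uword K) {
  vec g = grad;
  for (uword j = K; j < theta.n_elem; ++j) {
    double l = lam[j - K];
    if (theta[j] != 0.0) {
      g[j] = grad[j] - l * ((theta[j] > 0) ? 1.0 : -1.0);
    } else if (std::abs(grad[j]) > l) {
      g[j] = grad[j] - l * ((grad[j] > 0) ? 1.0 : -1.0);
    } else {
      g[j] = 0.0;
    }
  }
  return g;
}

static double kkt_violation(const vec& grad, const vec& theta, const vec& lam,
                            uword K) {
  double worst = 0.0;
  for (uword j = 0; j < K; ++j) worst = std::max(worst, std::abs(grad[j]));
  for (uword j = K; j < theta.n_elem; ++j) {
    double l = lam[j - K];
    double v = (theta[j] == 0.0)
                   ? std::max(0.0, std::abs(grad[j]) - l)
                   : std::abs(grad[j] - l * ((theta[j] > 0) ? 1.0 : -1.0));
    worst = std::max(worst, v);
  }
  return worst;
}

// One Newton step on the coordinates currently active (all intercepts plus
// nonzero betas), using the expected information restricted to that set and
// clamped so no beta crosses zero. Used to polish the solution once the
// gradient phase has flattened; returns false when no ascent was possible.
static bool newton_polish(const mat& X, const uvec& cl, const vec& lam,
                          uword K, vec& theta, double& obj, mat& L, mat& S,
                          vec& q, vec& pi, const vec& y) {
  const uword p = X.n_cols;
  std::vector<uword> act_v;
  for (uword j = 0; j < K; ++j) act_v.push_back(j);
  for (uword j = K; j < K + p; ++j) if (theta[j] != 0.0) act_v.push_back(j);
  uvec act = conv_to<uvec>::from(act_v);
  mat W;
  build_W(X, cl, S, W);
  vec v = clamp(pi % (1.0 - pi), 1e-10, 0.25);
  mat WA = W.cols(act);
  vec gpen = WA.t() * (y - pi);
  for (uword a = K; a < act.n_elem; ++a) {
    uword j = act[a];
    gpen[a] -= lam[j - K] * ((theta[j] > 0) ? 1.0 : -1.0);
  }
  mat info = WA.t() * (WA.each_col() % v);
  info.diag() += 1e-8;
  vec delta;
  if (!solve(delta, info, gpen, solve_opts::no_approx) || !delta.is_finite())
    return false;
  // clamp the step so no active beta flips sign within it
  double s = 1.0;
  for (uword a = K; a < act.n_elem; ++a) {
    uword j = act[a];
    if (delta[a] != 0.0 && ((theta[j] > 0) != (delta[a] > 0))) {
      s = std::min(s, -theta[j] / delta[a]);
    }
  }
  vec lam_full = lam;
  for (int h = 0; h < 20; ++h) {
    vec theta_new = theta;
    for (uword a = 0; a < act.n_elem; ++a) {
      theta_new[act[a]] += s * delta[a];
      if (act[a] >= K && theta[act[a]] != 0.0 &&
          ((theta_new[act[a]] > 0) != (theta[act[a]] > 0)))
        theta_new[act[a]] = 0.0;
    }
    mat L2, S2; vec q2, pi2;
    ql_forward(X, cl, theta_new.head(K), theta_new.tail(p), L2, S2, q2, pi2);
    double obj_new = bernoulli_ll(y, q2) - dot(lam, abs(theta_new.tail(p)));
    if (obj_new >= obj - 1e-12) {
      theta = theta_new; obj = obj_new; L = L2; S = S2; q = q2; pi = pi2;
      return true;
    }
    s *= 0.5;
  }
  return false;
}

// Directional-derivative gradient ascent for the L1-penalized quasi-linear
// logistic likelihood: theta <- theta + min(t_opt, t_edge) g(theta), where
// t_edge stops any beta coordinate from crossing zero within a step and
// t_opt is the one-dimensional Newton step along g under the expected
// information. Once the objective flattens, active-set Newton steps polish
// the iterate until the KKT conditions hold. lam holds the per-marker
// penalty lambda_{k(j)}.
// [[Rcpp::export]]
Rcpp::List cpp_fit_lasso(const arma::mat& X, const arma::vec& y,
                         const arma::uvec& cl, const arma::vec& alpha0,
                         const arma::vec& beta0, const arma::vec& lam,
                         double tol, int max_iter, double kkt_tol) {
  const uword K = alpha0.n_elem, p = X.n_cols;
  vec theta = join_cols(alpha0, beta0);
  mat L, S, W;
  vec q, pi;
  std::vector<double> trace;
  bool converged = false;
  ql_forward(X, cl, theta.head(K), theta.tail(p), L, S, q, pi);
  double obj = bernoulli_ll(y, q) - dot(lam, abs(theta.tail(p)));
  trace.push_back(obj);
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    build_W(X, cl, S, W);
    vec grad = W.t() * (y - pi);
    if (kkt_violation(grad, theta, lam, K) < kkt_tol) { converged = true; break; }
    vec g = lasso_direction(grad, theta, lam, K);
    double gg = dot(g, g);
    if (gg <= 0.0) { converged = true; break; }
    // t_opt: Newton step along g with expected-information curvature
    vec v = clamp(pi % (1.0 - pi), 1e-10, 0.25);
    vec Wg = W * g;
    double denom = std::abs(dot(v, square(Wg)));
    double t_opt = (denom > 0) ? gg / denom : 1.0;
    // t_edge: first zero crossing among beta coordinates moving toward 0
    double t_edge = datum::inf;
    for (uword j = K; j < theta.n_elem; ++j) {
      if (theta[j] != 0.0 && g[j] != 0.0 &&
          ((theta[j] > 0) != (g[j] > 0))) {
        t_edge = std::min(t_edge, -theta[j] / g[j]);
      }
    }
    double t = std::min(t_opt, t_edge);
    double obj_new = -datum::inf;
    vec theta_new;
    int h = 0;
    for (h = 0; h < 30; ++h) {
      theta_new = theta + t * g;
      // coordinates that reach the boundary land exactly on zero
      for (uword j = K; j < theta.n_elem; ++j) {
        if (theta[j] != 0.0 &&
            ((theta_new[j] > 0) != (theta[j] > 0) || theta_new[j] == 0.0 ||
             std::abs(theta_new[j]) < 1e-14 * std::abs(theta[j]))) {
          if ((theta_new[j] > 0) != (theta[j] > 0) || theta_new[j] == 0.0)
            theta_new[j] = 0.0;
        }
      }
      ql_forward(X, cl, theta_new.head(K), theta_new.tail(p), L, S, q, pi);
      obj_new = bernoulli_ll(y, q) - dot(lam, abs(theta_new.tail(p)));
      if (obj_new >= obj - 1e-12) break;
      t *= 0.5;
    }
    if (obj_new < obj - 1e-12) { // stuck: treat as converged at best iterate
      ql_forward(X, cl, theta.head(K), theta.tail(p), L, S, q, pi);
      break;
    }
    double rel = std::abs(obj_new - obj) / (std::abs(obj) + 1e-10);
    theta = theta_new;
    obj = obj_new;
    trace.push_back(obj);
    if (rel < tol) {
      // objective has flattened: polish on the active set until the KKT
      // conditions hold or an inactive coordinate needs to re-enter
      int polish = 0;
      for (polish = 0; polish < 200 && it + polish < max_iter; ++polish) {
        build_W(X, cl, S, W);
        vec grad2 = W.t() * (y - pi);
        if (kkt_violation(grad2, theta, lam, K) < kkt_tol) {
          converged = true; break;
        }
        vec g2 = lasso_direction(grad2, theta, lam, K);
        bool inactive_violated = false;
        for (uword j = K; j < theta.n_elem; ++j) {
          if (theta[j] == 0.0 && g2[j] != 0.0) { inactive_violated = true; break; }
        }
        if (inactive_violated) break; // resume gradient phase
        if (!newton_polish(X, cl, lam, K, theta, obj, L, S, q, pi, y)) break;
        trace.push_back(obj);
      }
      it += polish;
      if (converged) { ++it; break; }
    }
  }
  if (!converged) { // final KKT check at the last iterate
    build_W(X, cl, S, W);
    vec gradf = W.t() * (y - pi);
    converged = kkt_violation(gradf, theta, lam, K) < kkt_tol;
  }
  return Rcpp::List::create(
      Rcpp::Named("alpha") = theta.head(K), Rcpp::Named("beta") = theta.tail(p),
      Rcpp::Named("trace") = trace, Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = it);
}

// Log-likelihood of a parameter vector on (possibly held-out) data;
// used by cross-validation.
// [[Rcpp::export]]
double cpp_ql_loglik(const arma::mat& X, const arma::vec& y,
                     const arma::uvec& cl, const arma::vec& alpha,
                     const arma::vec& beta) {
  mat L, S;
  vec q, pi;
  ql_forward(X, cl, alpha, beta, L, S, q, pi);
  return bernoulli_ll(y, q);
}
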