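// Proximal-gradient solver for penalized multinomial logistic regression.
//
// Symmetric (reference-free) softmax parameterization: one coefficient
// column per class; the penalty resolves the identifiability redundancy.
// Smooth part f(B, b0) = (1/n) * sum_i [ logsumexp(x_i B + b0) - (x_i B + b0)_{y_i} ],
// penalty lambda * sum_jk |B_jk| (lasso) or lambda * sum_j ||B_j.||_2
// (group lasso, rows grouped across classes). Intercepts unpenalized.
// Backtracking guarantees a monotonically non-increasing objective.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double smooth_loss(const mat& S, const mat& Y) {
  // S: n x K linear scores, Y: n x K indicator
  vec m = max(S, 1);
  vec lse = m + log(sum(exp(S.each_col() - m), 1));
  return (accu(lse) - accu(S % Y)) / S.n_rows;
}

static mat softmax_rows(const mat& S) {
  mat P = S;
  P.each_col() -= max(S, 1);
  P = exp(P);
  P.each_col() /= sum(P, 1);
  return P;
}

static double penalty_value(const mat& B, const int kind) {
  if (kind == 0) return accu(abs(B));
  double s = 0.0;
  for (uword j = 0; j < B.n_rows; ++j) s += norm(B.row(j), 2);
  return s;
}

static mat prox(const mat& Z, const double thr, const int kind) {
  if (kind == 0) return sign(Z) % max(abs(Z) - thr, zeros(size(Z)));
  mat out(size(Z), fill::zeros);
  for (uword j = 0; j < Z.n_rows; ++j) {
    double nrm = norm(Z.row(j), 2);
    if (nrm > thr) out.row(j) = Z.row(j) * (1.0 - thr / nrm);
  }
  return out;
}

// KKT residual of the current iterate, given the smooth gradient
static double kkt_residual(const mat& G, const rowvec& g0, const mat& B,
                           const double lam, const int kind) {
  double r = abs(g0).max();
  if (kind == 0) {
    for (uword i = 0; i < B.n_elem; ++i) {
      double g = G(i);
      double ri = (B(i) == 0.0) ? std::max(std::abs(g) - lam, 0.0)
                                : std::abs(g + lam * ((B(i) > 0) ? 1.0 : -1.0));
      if (ri > r) r = ri;
    }
  } else {
    for (uword j = 0; j < B.n_rows; ++j) {
      double bn = norm(B.row(j), 2);
      double ri = (bn == 0.0)
        ? std::max(norm(G.row(j), 2) - lam, 0.0)
        : norm(G.row(j) + lam * B.row(j) / bn, 2);
      if (ri > r) r = ri;
    }
  }
  return r;
}

// [[Rcpp::export]]
Rcpp::List multinom_prox_path(const arma::mat& X, const arma::mat& Y,
                              const arma::vec& lambda, const int penalty,
                              const double tol, const int maxit,
                              const bool trace, const double kkt_tol) {
  const uword n = X.n_rows, p = X.n_cols, K = Y.n_cols, L = lambda.n_elem;

  cube beta(p, K, L, fill::zeros);
  mat b0path(K, L, fill::zeros);
  vec objs(L), iters(L);
  Rcpp::List traces(L);

  // warm start at the symmetric null model
  rowvec freq = mean(Y, 0);
  rowvec b0r = log(freq);
  b0r -= mean(b0r);

  mat B(p, K, fill::zeros);
  double step = 1.0;

  for (uword l = 0; l < L; ++l) {
    const double lam = lambda(l);
    std::vector<double> tr;
    mat S = X * B;
    S.each_row() += b0r;
    double f = smooth_loss(S, Y);
    double obj = f + lam * penalty_value(B, penalty);
    if (trace) tr.push_back(obj);

    int it = 0;
    bool converged = false;
    for (; it < maxit; ++it) {
      mat P = softmax_rows(S);
      mat E = (P - Y) / (double)n;
      mat G = X.t() * E;           // p x K smooth gradient wrt B
      rowvec g0 = sum(E, 0);       // intercept gradient

      if (it > 0 && converged &&
          kkt_residual(G, g0, B, lam, penalty) < kkt_tol) break;

      double t = step;
      mat Bn;
      rowvec b0n;
      double fn = 0.0;
      for (int bt = 0; bt < 60; ++bt) {
        Bn = prox(B - t * G, t * lam, penalty);
        b0n = b0r - t * g0;
        mat Sn = X * Bn;
        Sn.each_row() += b0n;
        fn = smooth_loss(Sn, Y);
        mat dB = Bn - B;
        rowvec d0 = b0n - b0r;
        double lin = f + accu(G % dB) + dot(g0, d0) +
          (accu(dB % dB) + dot(d0, d0)) / (2.0 * t);
        if (fn <= lin + 1e-12) { S = Sn; break; }
        t *= 0.5;
      }
      step = t * 1.5;
      if (step > 1e4) step = 1e4;

      double obj_new = fn + lam * penalty_value(Bn, penalty);
      B = Bn;
      b0r = b0n;
      f = fn;
      if (trace) tr.push_back(obj_new);
      converged = std::abs(obj - obj_new) <= tol * (std::abs(obj) + 1e-10);
      obj = obj_new;
    }

    beta.slice(l) = B;
    b0path.col(l) = b0r.t();
    objs(l) = obj;
    iters(l) = it;
    if (trace) traces[l] = Rcpp::wrap(tr);
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("b0") = b0path,
    Rcpp::Named("objective") = objs,
    Rcpp::Named("iterations") = iters);
  if (trace) out["trace"] = traces;
  return out;
}
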