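// Radial-basis-kernel C-SVC solved by SMO with maximal-violating-pair
// working-set selection (the classical dual decomposition). Deterministic:
// no randomness, ties resolved by lowest index. Per-class penalty weights
// support the heavily imbalanced AFP/non-AFP training sets.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat rbf_kernel(const mat& A, const mat& B, double gamma) {
  vec an = sum(square(A), 1);
  vec bn = sum(square(B), 1);
  mat D = repmat(an, 1, B.n_rows) + repmat(bn.t(), A.n_rows, 1)
          - 2.0 * (A * B.t());
  D.transform([gamma](double d) { return std::exp(-gamma * std::max(d, 0.0)); });
  return D;
}

struct SmoFit {
  vec alpha;
  double rho;
  int iter;
};

static SmoFit smo_solve(const mat& K, const vec& y, double C, double wpos,
                        double eps, int max_iter) {
  const int n = y.n_elem;
  vec Cvec(n);
  for (int i = 0; i < n; ++i) Cvec[i] = (y[i] > 0) ? C * wpos : C;
  vec alpha(n, fill::zeros);
  vec G(n, fill::ones);
  G *= -1.0;  // gradient of the dual objective, G_t = (Q alpha)_t - 1

  int it = 0;
  for (; it < max_iter; ++it) {
    // select maximal violating pair
    int i = -1, j = -1;
    double gmax = -datum::inf, gmin = datum::inf;
    for (int t = 0; t < n; ++t) {
      if ((y[t] > 0 && alpha[t] < Cvec[t]) || (y[t] < 0 && alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v > gmax) { gmax = v; i = t; }
      }
      if ((y[t] < 0 && alpha[t] < Cvec[t]) || (y[t] > 0 && alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v < gmin) { gmin = v; j = t; }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    // move along the feasible direction d_i = y_i, d_j = -y_j (preserves
    // y^T alpha); step length from the one-dimensional minimizer
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double ai = alpha[i], aj = alpha[j];
    double step = (gmax - gmin) / quad;
    double s = y[i] * ai + y[j] * aj;  // conserved
    double new_ai = ai + y[i] * step;
    double new_aj = aj - y[j] * step;
    // clip to the box while keeping y_i a_i + y_j a_j = s
    new_ai = std::min(std::max(new_ai, 0.0), Cvec[i]);
    new_aj = y[j] * (s - y[i] * new_ai);
    new_aj = std::min(std::max(new_aj, 0.0), Cvec[j]);
    new_ai = y[i] * (s - y[j] * new_aj);
    new_ai = std::min(std::max(new_ai, 0.0), Cvec[i]);
    double dai = new_ai - ai, daj = new_aj - aj;
    if (std::abs(dai) < 1e-14 && std::abs(daj) < 1e-14) break;
    // gradient update: G += Q_col_i * dai + Q_col_j * daj, Q_ts = y_t y_s K_ts
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
    alpha[i] = new_ai;
    alpha[j] = new_aj;
  }

  // rho from KKT conditions (LIBSVM-style)
  double ub = datum::inf, lb = -datum::inf, sum_free = 0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= Cvec[t] - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      sum_free += yG;
      ++n_free;
    }
  }
  double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;
  return SmoFit{alpha, rho, it};
}

// [[Rcpp::export(name = ".svm_train_cpp")]]
Rcpp::List svm_train_cpp(const arma::mat& X, const arma::vec& y, double C,
                         double gamma, double wpos, double eps = 1e-3,
                         int max_iter = 200000) {
  mat K = rbf_kernel(X, X, gamma);
  SmoFit fit = smo_solve(K, y, C, wpos, eps, max_iter);
  uvec sv = find(fit.alpha > 1e-12);
  Rcpp::IntegerVector sv_index(sv.n_elem);
  for (uword t = 0; t < sv.n_elem; ++t) sv_index[t] = (int)sv[t];
  vec alpha_sv = fit.alpha.elem(sv);
  vec y_sv = y.elem(sv);
  return Rcpp::List::create(
      Rcpp::Named("alpha") = alpha_sv,
      Rcpp::Named("sv_index") = sv_index,
      Rcpp::Named("sv_y") = y_sv,
      Rcpp::Named("rho") = fit.rho,
      Rcpp::Named("iterations") = fit.iter);
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
arma::vec svm_decision_cpp(const arma::mat& SV, const arma::vec& coef,
                           double rho, double gamma, const arma::mat& Xnew) {
  mat K = rbf_kernel(Xnew, SV, gamma);
  return K * coef - rho;
}

// k-fold cross-validated confusion counts, fully in C++ so genetic-algorithm
// fitness evaluation stays fast. fold: 1-based fold id per row.
// [[Rcpp::export(name = ".svm_cv_counts_cpp")]]
Rcpp::IntegerVector svm_cv_counts_cpp(const arma::mat& X, const arma::vec& y,
                                      const arma::ivec& fold, double C,
                                      double gamma, double wpos,
                                      double eps = 1e-3,
                                      int max_iter = 200000) {
  int tp = 0, tn = 0, fp = 0, fn = 0;
  int kmax = fold.max();
  for (int k = 1; k <= kmax; ++k) {
    uvec te = find(fold == k);
    uvec tr = find(fold != k);
    if (te.n_elem == 0) continue;
    mat Xtr = X.rows(tr);
    vec ytr = y.elem(tr);
    mat Ktr = rbf_kernel(Xtr, Xtr, gamma);
    SmoFit fit = smo_solve(Ktr, ytr, C, wpos, eps, max_iter);
    uvec sv = find(fit.alpha > 1e-12);
    vec scores;
    if (sv.n_elem == 0) {
      scores = vec(te.n_elem, fill::zeros);
      scores -= fit.rho;
    } else {
      mat Kte = rbf_kernel(X.rows(te), Xtr.rows(sv), gamma);
      scores = Kte * (fit.alpha.elem(sv) % ytr.elem(sv)) - fit.rho;
    }
    for (uword t = 0; t < te.n_elem; ++t) {
      bool pred = scores[t] > 0;
      bool truth = y[te[t]] > 0;
      if (pred && truth) ++tp;
      else if (!pred && !truth) ++tn;
      else if (pred && !truth) ++fp;
      else ++fn;
    }
  }
  return Rcpp::IntegerVector::create(tp, tn, fp, fn);
}
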