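// C-support-vector classification with RBF kernel, solved by SMO with
// maximal-violating-pair working-set selection (Keerthi et al. / LIBSVM-style
// first-order selection, stopping tolerance eps on the duality-gap proxy).
// Implemented here because the package must run without an external SVM
// library; defaults mirror the classic e1071/libsvm ones (C = 1,
// gamma = 1/n_features, z-score feature scaling).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TAU = 1e-12;

// RBF kernel matrix between rows of A (n x p) and rows of B (m x p).
static arma::mat rbf_kernel(const arma::mat& A, const arma::mat& B,
                            double gamma) {
  arma::vec an = arma::sum(arma::square(A), 1);
  arma::vec bn = arma::sum(arma::square(B), 1);
  arma::mat D = arma::repmat(an, 1, B.n_rows) +
                arma::repmat(bn.t(), A.n_rows, 1) - 2.0 * A * B.t();
  D.transform([gamma](double d) { return std::exp(-gamma * std::max(d, 0.0)); });
  return D;
}

// Solve: min 1/2 a'Qa - e'a  s.t. 0 <= a <= C, y'a = 0, with Q_ij = y_i y_j K_ij.
// Returns alpha and the intercept b of f(x) = sum_i alpha_i y_i K(x_i, x) + b.
static void smo_solve(const arma::mat& K, const arma::ivec& y, double C,
                      double eps, int max_iter,
                      arma::vec& alpha, double& b) {
  const int n = K.n_rows;
  alpha.zeros(n);
  arma::vec G(n, arma::fill::value(-1.0));  // gradient of the dual objective

  int iter = 0;
  while (iter++ < max_iter) {
    // working-set selection: maximal violating pair
    int i = -1, j = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * (y[i] * y[j]) * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t)
      G[t] += (y[t] * y[i]) * K(t, i) * dai + (y[t] * y[j]) * K(t, j) * daj;
  }

  // intercept from the KKT conditions: b = -y_i G_i averaged over the
  // current violating-pair bounds
  double Gmax = -std::numeric_limits<double>::infinity();
  double Gmin = std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
    bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
    double v = -y[t] * G[t];
    if (up && v > Gmax) Gmax = v;
    if (low && v < Gmin) Gmin = v;
  }
  b = (Gmax + Gmin) / 2.0;
}

// [[Rcpp::export(name = ".svm_train_cpp")]]
List svm_train_cpp(const arma::mat& X, const arma::ivec& y, double cost,
                   double gamma, double eps = 1e-3, int max_iter = 100000) {
  arma::mat K = rbf_kernel(X, X, gamma);
  arma::vec alpha;
  double b;
  smo_solve(K, y, cost, eps, max_iter, alpha, b);
  return List::create(_["alpha"] = alpha, _["b"] = b);
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
arma::vec svm_decision_cpp(const arma::mat& Xtrain, const arma::ivec& y,
                           const arma::vec& alpha, double b,
                           const arma::mat& Xnew, double gamma) {
  arma::mat K = rbf_kernel(Xnew, Xtrain, gamma);
  arma::vec coef = alpha % arma::conv_to<arma::vec>::from(y);
  return K * coef + b;
}

// Leave-one-out cross-validation over the samples (rows of X). Feature
// scaling, when requested, is refitted inside every fold on the n-1 training
// rows only; a zero-variance feature within a fold is centered but not
// rescaled. Returns the decision value for each held-out sample.
// [[Rcpp::export(name = ".svm_loocv_cpp")]]
arma::vec svm_loocv_cpp(const arma::mat& X, const arma::ivec& y, double cost,
                        double gamma_in, bool scale, bool gamma_auto,
                        double eps = 1e-3, int max_iter = 100000) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec dec(n);
  double gamma = gamma_auto ? 1.0 / p : gamma_in;
  for (int hold = 0; hold < n; ++hold) {
    arma::uvec idx(n - 1);
    for (int t = 0, k = 0; t < n; ++t)
      if (t != hold) idx[k++] = t;
    arma::mat Xtr = X.rows(idx);
    arma::mat Xte = X.row(hold);
    if (scale) {
      arma::rowvec mu = arma::mean(Xtr, 0);
      arma::rowvec sd = arma::stddev(Xtr, 0, 0);  // n-1 denominator
      sd.transform([](double v) { return v > 0 ? v : 1.0; });
      Xtr.each_row() -= mu;
      Xtr.each_row() /= sd;
      Xte.each_row() -= mu;
      Xte.each_row() /= sd;
    }
    arma::ivec ytr = y.elem(idx);
    arma::mat K = rbf_kernel(Xtr, Xtr, gamma);
    arma::vec alpha;
    double b;
    smo_solve(K, ytr, cost, eps, max_iter, alpha, b);
    arma::mat Kte = rbf_kernel(Xte, Xtr, gamma);
    arma::vec coef = alpha % arma::conv_to<arma::vec>::from(ytr);
    dec[hold] = arma::as_scalar(Kte * coef) + b;
  }
  return dec;
}
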