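// Covariance-form SIMPLS kernel for cross-validated PLS1 regression.
//
// IRIV evaluates on the order of 1e5 five-fold PLS models per round, so the
// cross-validation loop precomputes, once per fold, the centered Gram matrix
// X'X and cross-product X'y on the training rows.  Each randomized sub-model
// then runs SIMPLS entirely on the corresponding submatrices, making the cost
// per sub-model independent of the number of samples.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct FoldStats {
  uvec test_rows;   // 0-based rows held out
  uword n_train;
  vec xmean;        // p
  double ymean;
  mat G;            // centered X'X over train rows (p x p)
  vec xty;          // centered X'y over train rows (p)
};

std::vector<FoldStats> fold_stats(const mat& X, const vec& y,
                                  const ivec& folds) {
  const int k = folds.max();
  std::vector<FoldStats> out;
  out.reserve(k);
  for (int f = 1; f <= k; ++f) {
    FoldStats fs;
    fs.test_rows = find(folds == f);
    uvec train = find(folds != f);
    fs.n_train = train.n_elem;
    mat Xt = X.rows(train);
    vec yt = y.elem(train);
    fs.xmean = mean(Xt, 0).t();
    fs.ymean = mean(yt);
    fs.G = Xt.t() * Xt - double(fs.n_train) * (fs.xmean * fs.xmean.t());
    fs.xty = Xt.t() * yt - double(fs.n_train) * fs.xmean * fs.ymean;
    out.push_back(std::move(fs));
  }
  return out;
}

// SIMPLS coefficient path from the centered covariance matrices.
// G = X'X (s x s), s0 = X'y (s); column a-1 holds the cumulative
// regression vector with a latent variables.  Returns the number of
// components actually extracted (may stop early on rank deficiency);
// remaining columns repeat the last valid vector.
int simpls_path(const mat& G, const vec& s0, int ncomp, mat& beta) {
  const uword p = G.n_rows;
  beta.zeros(p, std::max(ncomp, 1));
  if (ncomp < 1) return 0;
  mat V(p, ncomp, fill::none);
  vec s = s0;
  vec b(p, fill::zeros);
  const double tol = 1e-12 * std::max(1.0, trace(G));
  int used = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec r = s;
    vec pl = G * r;
    double tt = dot(r, pl);
    if (!std::isfinite(tt) || tt < tol) break;
    double normt = std::sqrt(tt);
    r /= normt;
    pl /= normt;                  // loadings X't
    double qa = dot(s0, r);       // y't (y never deflated in PLS1 SIMPLS)
    b += r * qa;
    beta.col(a) = b;
    ++used;
    vec v = pl;
    if (a > 0) {
      vec tmp = V.head_cols(a).t() * pl;
      v -= V.head_cols(a) * tmp;
    }
    double nv = norm(v);
    if (nv < 1e-12) break;        // loading space exhausted
    v /= nv;
    V.col(a) = v;
    s -= v * dot(v, s);
  }
  for (int a = used; a < ncomp; ++a) beta.col(a) = b;
  return used;
}

// Pooled k-fold RMSECV of the variable subset `incl` (0-based columns):
// the cross-validated error curve over 1..max_factors latent variables is
// pooled across folds and its minimum is returned (the usual RMSECV-curve
// criterion; the factor count is selected by the cross-validation itself,
// capped at max_factors).
double rmsecv_subset(const mat& X, const vec& y,
                     const std::vector<FoldStats>& fls,
                     const uvec& incl, int max_factors) {
  if (incl.n_elem == 0) return datum::inf;
  int A = std::min<int>(max_factors, incl.n_elem);
  for (const FoldStats& fs : fls)
    if (fs.n_train < 2) return datum::inf;
  vec sse(A, fill::zeros);
  uword n = 0;
  mat beta;
  for (const FoldStats& fs : fls) {
    int Af = std::min<int>(A, fs.n_train - 1);
    mat Gs = fs.G.submat(incl, incl);
    vec s0 = fs.xty.elem(incl);
    simpls_path(Gs, s0, Af, beta);
    if (beta.n_cols < (uword)A) {            // pad when fold supports fewer
      mat full(beta.n_rows, A);
      for (int a = 0; a < A; ++a)
        full.col(a) = beta.col(std::min<int>(a, beta.n_cols - 1));
      beta = full;
    }
    vec xm = fs.xmean.elem(incl);
    for (uword t = 0; t < fs.test_rows.n_elem; ++t) {
      uword row = fs.test_rows(t);
      rowvec xr = X.row(row);
      vec xc(incl.n_elem);
      for (uword j = 0; j < incl.n_elem; ++j)
        xc(j) = xr(incl(j)) - xm(j);
      rowvec preds = xc.t() * beta;          // prediction per component count
      for (int a = 0; a < A; ++a) {
        double e = fs.ymean + preds(a) - y(row);
        sse(a) += e * e;
      }
      ++n;
    }
  }
  return std::sqrt(sse.min() / double(n));
}

uvec row_to_incl(const imat& A, uword k, bool flip, uword flip_col) {
  std::vector<uword> idx;
  idx.reserve(A.n_cols);
  for (uword j = 0; j < A.n_cols; ++j) {
    int v = A(k, j);
    if (flip && j == flip_col) v = 1 - v;
    if (v == 1) idx.push_back(j);
  }
  return uvec(idx);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cppDesignRmsecv")]]
arma::vec cpp_design_rmsecv(const arma::mat& X, const arma::vec& y,
                            const arma::imat& A, const arma::ivec& folds,
                            int max_factors) {
  std::vector<FoldStats> fls = fold_stats(X, y, folds);
  vec out(A.n_rows);
  for (uword k = 0; k < A.n_rows; ++k)
    out(k) = rmsecv_subset(X, y, fls, row_to_incl(A, k, false, 0),
                           max_factors);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cppScoreAll")]]
Rcpp::List cpp_score_all(const arma::mat& X, const arma::vec& y,
                         const arma::imat& A, const arma::ivec& folds,
                         int max_factors) {
  std::vector<FoldStats> fls = fold_stats(X, y, folds);
  const uword m = A.n_rows, p = A.n_cols;
  vec rmsecv0(m);
  for (uword k = 0; k < m; ++k)
    rmsecv0(k) = rmsecv_subset(X, y, fls, row_to_incl(A, k, false, 0),
                               max_factors);
  mat rmsecvi(m, p);
  for (uword j = 0; j < p; ++j) {
    for (uword k = 0; k < m; ++k)
      rmsecvi(k, j) = rmsecv_subset(X, y, fls, row_to_incl(A, k, true, j),
                                    max_factors);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("rmsecv0") = rmsecv0,
                            Rcpp::Named("rmsecvi") = rmsecvi);
}

//' @noRd
// [[Rcpp::export(name = ".cppSubsetRmsecv")]]
double cpp_subset_rmsecv(const arma::mat& X, const arma::vec& y,
                         const arma::uvec& incl1, const arma::ivec& folds,
                         int max_factors) {
  std::vector<FoldStats> fls = fold_stats(X, y, folds);
  if (incl1.n_elem == 0) return datum::inf;
  return rmsecv_subset(X, y, fls, incl1 - 1, max_factors);
}

//' @noRd
// [[Rcpp::export(name = ".cppPlsCoef")]]
Rcpp::List cpp_pls_coef(const arma::mat& X, const arma::vec& y, int ncomp) {
  const uword n = X.n_rows, p = X.n_cols;
  vec xm = mean(X, 0).t();
  double ym = mean(y);
  mat G = X.t() * X - double(n) * (xm * xm.t());
  vec s0 = X.t() * y - double(n) * xm * ym;
  int a = std::min<int>(ncomp, std::min<int>(p, n - 1));
  mat path;
  int used = simpls_path(G, s0, a, path);
  vec beta = path.col(std::max(used, 1) - 1);
  a = used;
  double intercept = ym - dot(xm, beta);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("intercept") = intercept,
                            Rcpp::Named("ncomp") = a);
}
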