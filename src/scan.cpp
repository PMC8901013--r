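// Kernels for the chi-square interaction decomposition and the logistic
// interaction fits, shared by the observed scan and the permutation loop.
// A tuple's contingency structure (combined genotype indices per margin)
// is precomputed in R once; only the class labels change across
// permutations, so each permutation is a counting pass.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Chi2 {
  double stat;
  int df;
};

// Pearson chi2 of a margin (combined genotype index, values 0..m-1)
// against a binary label. All-zero rows are dropped; a table left with
// fewer than 2 non-empty rows or with an empty class column is
// degenerate: (0, 0).
static Chi2 chi2_assoc(const int *idx, int n, int m, const int *y) {
  std::vector<double> c0(m, 0.0), c1(m, 0.0);
  for (int i = 0; i < n; i++) {
    if (y[i]) c1[idx[i]]++; else c0[idx[i]]++;
  }
  double tot0 = 0, tot1 = 0;
  int rows = 0;
  for (int r = 0; r < m; r++) {
    double s = c0[r] + c1[r];
    if (s > 0) rows++;
    tot0 += c0[r];
    tot1 += c1[r];
  }
  Chi2 out = {0.0, 0};
  int cols = (tot0 > 0) + (tot1 > 0);
  if (rows < 2 || cols < 2) return out;
  double N = tot0 + tot1, stat = 0;
  for (int r = 0; r < m; r++) {
    double s = c0[r] + c1[r];
    if (s <= 0) continue;
    double e0 = s * tot0 / N, e1 = s * tot1 / N;
    stat += (c0[r] - e0) * (c0[r] - e0) / e0 +
            (c1[r] - e1) * (c1[r] - e1) / e1;
  }
  out.stat = stat;
  out.df = (rows - 1) * (cols - 1);
  return out;
}

// margins: k = 2 -> [A, B, AB]; k = 3 -> [A, B, C, AB, BC, AC, ABC];
// each an integer vector of combined indices with attribute-free size m.
struct TupleMargins {
  std::vector<const int *> idx;
  std::vector<int> m;
  int n;
  int order;
};

static TupleMargins unpackTuple(List tuple) {
  TupleMargins t;
  List margins = tuple["margins"];
  IntegerVector ms = tuple["m"];
  t.order = as<int>(tuple["order"]);
  for (int j = 0; j < margins.size(); j++) {
    IntegerVector v = margins[j];
    t.idx.push_back(INTEGER(v));
    t.m.push_back(ms[j]);
    t.n = v.size();
  }
  return t;
}

// interaction statistic and df per the decomposition:
// 2-SNP: X2[AxB] = X2[A+B] - X2[A] - X2[B] (df likewise);
// 3-SNP: X2[AxBxC] = X2[A+B+C] - X2[AxB] - X2[BxC] - X2[AxC]
//                    - X2[A] - X2[B] - X2[C], with each pairwise
// interaction itself the 2-SNP difference on the same subjects.
static void decompose(const TupleMargins &t, const int *y, double &stat,
                      int &df, std::vector<Chi2> *terms = nullptr) {
  int k = t.idx.size();
  std::vector<Chi2> cc(k);
  for (int j = 0; j < k; j++)
    cc[j] = chi2_assoc(t.idx[j], t.n, t.m[j], y);
  if (t.order == 2) {
    stat = cc[2].stat - cc[0].stat - cc[1].stat;
    df = cc[2].df - cc[0].df - cc[1].df;
  } else {
    double iAB = cc[3].stat - cc[0].stat - cc[1].stat;
    double iBC = cc[4].stat - cc[1].stat - cc[2].stat;
    double iAC = cc[5].stat - cc[0].stat - cc[2].stat;
    int dAB = cc[3].df - cc[0].df - cc[1].df;
    int dBC = cc[4].df - cc[1].df - cc[2].df;
    int dAC = cc[5].df - cc[0].df - cc[2].df;
    stat = cc[6].stat - iAB - iBC - iAC - cc[0].stat - cc[1].stat -
           cc[2].stat;
    df = cc[6].df - dAB - dBC - dAC - cc[0].df - cc[1].df - cc[2].df;
  }
  if (terms) *terms = cc;
}

static double neglog10p_chi2(double stat, int df) {
  if (df < 1) return NA_REAL;
  double s = stat > 0 ? stat : 0.0;
  return -R::pchisq(s, (double)df, 0, 1) / M_LN10;
}

// [[Rcpp::export(name = ".chi2DecomposeCpp")]]
List chi2_decompose_cpp(List tuple, IntegerVector y) {
  TupleMargins t = unpackTuple(tuple);
  double stat;
  int df;
  std::vector<Chi2> terms;
  decompose(t, INTEGER(y), stat, df, &terms);
  NumericVector ts(terms.size());
  IntegerVector tdf(terms.size());
  for (size_t j = 0; j < terms.size(); j++) {
    ts[j] = terms[j].stat;
    tdf[j] = terms[j].df;
  }
  return List::create(_["stat"] = stat, _["df"] = df,
                      _["term_stats"] = ts, _["term_dfs"] = tdf,
                      _["neglog10_p"] = neglog10p_chi2(stat, df));
}

// [[Rcpp::export(name = ".permChi2Cpp")]]
NumericMatrix perm_chi2_cpp(List tuples, IntegerMatrix permY) {
  int T = tuples.size(), B = permY.ncol();
  std::vector<TupleMargins> tt(T);
  std::vector<std::vector<int>> subj(T);
  for (int t = 0; t < T; t++) {
    List tp = tuples[t];
    tt[t] = unpackTuple(tp);
    IntegerVector s = tp["subj"];   // 0-based indices into the label vector
    subj[t] = std::vector<int>(s.begin(), s.end());
  }
  NumericMatrix out(B, T);
  for (int b = 0; b < B; b++) {
    const int *yfull = &permY(0, b);
    for (int t = 0; t < T; t++) {
      int n = subj[t].size();
      std::vector<int> y(n);
      for (int i = 0; i < n; i++) y[i] = yfull[subj[t][i]];
      double stat;
      int df;
      decompose(tt[t], y.data(), stat, df);
      out(b, t) = neglog10p_chi2(stat, df);
    }
  }
  return out;
}

// ---- logistic regression (IRLS, Cholesky solve; p is tiny) -------------

static bool chol_solve(std::vector<double> &A, std::vector<double> &b,
                       int p, std::vector<double> *Ainv = nullptr) {
  // A symmetric p x p (column-major), overwritten by its Cholesky factor
  for (int j = 0; j < p; j++) {
    double d = A[j * p + j];
    for (int k = 0; k < j; k++) d -= A[j * p + k] * A[j * p + k];
    if (d <= 1e-12) return false;
    d = std::sqrt(d);
    A[j * p + j] = d;
    for (int i = j + 1; i < p; i++) {
      double s = A[i * p + j];
      for (int k = 0; k < j; k++) s -= A[i * p + k] * A[j * p + k];
      A[i * p + j] = s / d;
    }
  }
  // solve L L' x = b
  for (int i = 0; i < p; i++) {
    double s = b[i];
    for (int k = 0; k < i; k++) s -= A[i * p + k] * b[k];
    b[i] = s / A[i * p + i];
  }
  for (int i = p - 1; i >= 0; i--) {
    double s = b[i];
    for (int k = i + 1; k < p; k++) s -= A[k * p + i] * b[k];
    b[i] = s / A[i * p + i];
  }
  if (Ainv) {
    // invert via L: Ainv = (L L')^{-1}
    std::vector<double> inv(p * p, 0.0);
    for (int col = 0; col < p; col++) {
      std::vector<double> e(p, 0.0);
      e[col] = 1.0;
      for (int i = 0; i < p; i++) {
        double s = e[i];
        for (int k = 0; k < i; k++) s -= A[i * p + k] * e[k];
        e[i] = s / A[i * p + i];
      }
      for (int i = p - 1; i >= 0; i--) {
        double s = e[i];
        for (int k = i + 1; k < p; k++) s -= A[k * p + i] * e[k];
        e[i] = s / A[i * p + i];
      }
      for (int i = 0; i < p; i++) inv[col * p + i] = e[i];
    }
    *Ainv = inv;
  }
  return true;
}

struct IrlsFit {
  std::vector<double> beta, se;
  bool converged, singular, separation;
};

static IrlsFit irls(const double *X, int n, int p, const int *y,
                    int maxit = 30, double tol = 1e-8) {
  IrlsFit fit;
  fit.beta.assign(p, 0.0);
  fit.se.assign(p, NA_REAL);
  fit.converged = false;
  fit.singular = false;
  fit.separation = false;
  // warm start at the intercept-only solution (column 0 is the intercept)
  double ybar = 0;
  for (int i = 0; i < n; i++) ybar += y[i];
  ybar /= n;
  if (ybar <= 0 || ybar >= 1) {
    fit.singular = true;   // one class absent: no usable fit
    return fit;
  }
  fit.beta[0] = std::log(ybar / (1 - ybar));
  std::vector<double> eta(n, fit.beta[0]), XtWX(p * p), rhs(p), row(p);
  for (int it = 0; it < maxit; it++) {
    std::fill(XtWX.begin(), XtWX.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    for (int i = 0; i < n; i++) {
      double e = eta[i];
      double mu = 1.0 / (1.0 + std::exp(-e));
      double w = mu * (1.0 - mu);
      if (w < 1e-10) w = 1e-10;
      double wz = w * e + (y[i] - mu);   // w * working response
      for (int a = 0; a < p; a++) row[a] = X[a * n + i];
      for (int a = 0; a < p; a++) {
        rhs[a] += row[a] * wz;
        double wxa = w * row[a];
        double *col = &XtWX[a * p];
        for (int bq = a; bq < p; bq++) col[bq] += wxa * row[bq];
      }
    }
    for (int a = 0; a < p; a++)
      for (int bq = a + 1; bq < p; bq++)
        XtWX[bq * p + a] = XtWX[a * p + bq];
    std::vector<double> A = XtWX, bnew = rhs;
    if (!chol_solve(A, bnew, p)) {
      fit.singular = true;
      return fit;
    }
    double delta = 0;
    for (int a = 0; a < p; a++)
      delta = std::max(delta, std::fabs(bnew[a] - fit.beta[a]));
    fit.beta = bnew;
    double emax = 0;
    for (int i = 0; i < n; i++) {
      double e = 0;
      for (int a = 0; a < p; a++) e += X[a * n + i] * fit.beta[a];
      eta[i] = e;
      emax = std::max(emax, std::fabs(e));
    }
    if (emax > 30) fit.separation = true;
    if (delta < tol) {
      fit.converged = true;
      // Fisher information at the solution for the standard errors
      std::fill(XtWX.begin(), XtWX.end(), 0.0);
      for (int i = 0; i < n; i++) {
        double mu = 1.0 / (1.0 + std::exp(-eta[i]));
        double w = mu * (1.0 - mu);
        if (w < 1e-10) w = 1e-10;
        for (int a = 0; a < p; a++) row[a] = X[a * n + i];
        for (int a = 0; a < p; a++) {
          double wxa = w * row[a];
          double *col = &XtWX[a * p];
          for (int bq = a; bq < p; bq++) col[bq] += wxa * row[bq];
        }
      }
      for (int a = 0; a < p; a++)
        for (int bq = a + 1; bq < p; bq++)
          XtWX[bq * p + a] = XtWX[a * p + bq];
      std::vector<double> A2 = XtWX, dummy(p, 0.0), Ainv;
      if (!chol_solve(A2, dummy, p, &Ainv)) {
        fit.singular = true;
        return fit;
      }
      for (int a = 0; a < p; a++) fit.se[a] = std::sqrt(Ainv[a * p + a]);
      return fit;
    }
  }
  return fit;
}

// [[Rcpp::export(name = ".logisticIrlsCpp")]]
List logistic_irls_cpp(NumericMatrix X, IntegerVector y, int maxit = 30,
                       double tol = 1e-8) {
  IrlsFit fit = irls(REAL(X), X.nrow(), X.ncol(), INTEGER(y), maxit, tol);
  return List::create(
      _["beta"] = NumericVector(fit.beta.begin(), fit.beta.end()),
      _["se"] = NumericVector(fit.se.begin(), fit.se.end()),
      _["converged"] = fit.converged, _["singular"] = fit.singular,
      _["separation"] = fit.separation);
}

static double neglog10p_wald(const IrlsFit &fit) {
  if (fit.singular || !fit.converged || fit.separation) return NA_REAL;
  int p = fit.beta.size();
  double z = fit.beta[p - 1] / fit.se[p - 1];
  // two-sided: p = 2 * pnorm(-|z|); computed on log scale
  return -(R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 1) + M_LN2) / M_LN10;
}

// [[Rcpp::export(name = ".permLogisticCpp")]]
NumericMatrix perm_logistic_cpp(List tuples, IntegerMatrix permY) {
  int T = tuples.size(), B = permY.ncol();
  std::vector<NumericMatrix> Xs;
  std::vector<std::vector<int>> subj(T);
  for (int t = 0; t < T; t++) {
    List tp = tuples[t];
    NumericMatrix X = tp["X"];
    Xs.push_back(X);
    IntegerVector s = tp["subj"];
    subj[t] = std::vector<int>(s.begin(), s.end());
  }
  NumericMatrix out(B, T);
  for (int b = 0; b < B; b++) {
    const int *yfull = &permY(0, b);
    for (int t = 0; t < T; t++) {
      int n = subj[t].size();
      std::vector<int> y(n);
      for (int i = 0; i < n; i++) y[i] = yfull[subj[t][i]];
      // permutation stats need ~4 decimals on the -log10 p scale, so a
      // looser tolerance than the observed fits is enough
      IrlsFit fit =
          irls(REAL(Xs[t]), Xs[t].nrow(), Xs[t].ncol(), y.data(), 25, 1e-6);
      out(b, t) = neglog10p_wald(fit);
    }
  }
  return out;
}
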