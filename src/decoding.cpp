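#include <Rcpp.h>
using namespace Rcpp;

// Two-parameter logistic fit (intercept + slope) by IRLS on standardized
// training data; returns fold accuracy on the test set. Single-feature
// decoders need no regularization beyond the iteration cap: under perfect
// separation the coefficients are clamped once predictions saturate, which
// leaves test-set decisions unchanged.
static double fold_accuracy(const NumericVector& x, const IntegerVector& y,
                            const IntegerVector& folds, int fold) {
  int n = x.size();
  // training mean/sd
  double sum = 0.0, sum2 = 0.0;
  int ntr = 0, n1 = 0;
  for (int i = 0; i < n; ++i) {
    if (folds[i] == fold) continue;
    sum += x[i]; sum2 += x[i] * x[i];
    ++ntr;
    if (y[i] == 1) ++n1;
  }
  double mu = sum / ntr;
  double var = (sum2 - ntr * mu * mu) / (ntr - 1);
  double sd = var > 0 ? std::sqrt(var) : 0.0;

  int correct = 0, ntest = 0;
  if (sd < 1e-12) {
    // constant training feature: majority-class fallback; exact tie goes to
    // the class with the lower label index (0)
    int maj = (2 * n1 > ntr) ? 1 : 0;
    for (int i = 0; i < n; ++i) {
      if (folds[i] != fold) continue;
      ++ntest;
      if (y[i] == maj) ++correct;
    }
    return ntest ? (double)correct / ntest : NA_REAL;
  }

  double b0 = 0.0, b1 = 0.0;
  for (int it = 0; it < 50; ++it) {
    double sw = 0, swz = 0, swzz = 0, su = 0, suz = 0;
    for (int i = 0; i < n; ++i) {
      if (folds[i] == fold) continue;
      double z = (x[i] - mu) / sd;
      double eta = b0 + b1 * z;
      double p = 1.0 / (1.0 + std::exp(-eta));
      double w = p * (1.0 - p);
      if (w < 1e-10) w = 1e-10;
      double u = y[i] - p;
      sw += w; swz += w * z; swzz += w * z * z;
      su += u; suz += u * z;
    }
    // Newton step: solve [sw swz; swz swzz] * delta = [su; suz]
    double det = sw * swzz - swz * swz;
    if (std::fabs(det) < 1e-12) break;
    double d0 = (swzz * su - swz * suz) / det;
    double d1 = (sw * suz - swz * su) / det;
    b0 += d0; b1 += d1;
    if (std::fabs(b0) > 30.0 || std::fabs(b1) > 30.0) break;  // separation
    if (std::fabs(d0) < 1e-8 && std::fabs(d1) < 1e-8) break;
  }

  for (int i = 0; i < n; ++i) {
    if (folds[i] != fold) continue;
    ++ntest;
    double z = (x[i] - mu) / sd;
    double eta = b0 + b1 * z;
    // P > 0.5 <=> eta > 0; exact tie (eta == 0) resolves to class 0
    int pred = (eta > 0.0) ? 1 : 0;
    if (pred == y[i]) ++correct;
  }
  return ntest ? (double)correct / ntest : NA_REAL;
}

// [[Rcpp::export]]
double cpp_cv_da(NumericVector x, IntegerVector y, IntegerVector folds, int k) {
  double acc = 0.0;
  int used = 0;
  for (int f = 1; f <= k; ++f) {
    double a = fold_accuracy(x, y, folds, f);
    if (!ISNA(a)) { acc += a; ++used; }
  }
  return used ? acc / used : NA_REAL;
}

// [[Rcpp::export]]
NumericVector cpp_decode_matrix(NumericMatrix X, IntegerVector y,
                                IntegerVector folds, int k) {
  int p = X.ncol();
  NumericVector out(p);
  for (int j = 0; j < p; ++j) {
    NumericVector xj = X(_, j);
    out[j] = cpp_cv_da(xj, y, folds, k);
  }
  return out;
}
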