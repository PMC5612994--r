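#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear C-SVM (L1-loss, hinge) trained by dual coordinate descent on the
// box-constrained dual, with the bias absorbed as an augmented constant
// feature. Deterministic: fixed coordinate order, fixed stopping rule.
//
// buf: column-major n_total x d feature buffer (last column must be the
// bias column of ones, appended by the caller); idx: training row indices
// (0-based into buf); y: +1/-1 per training row. Writes w (length d).
static void dcd_train(const double *buf, int n_total, int d,
                      const std::vector<int> &idx, const std::vector<double> &y,
                      double C, std::vector<double> &w,
                      int max_epochs = 25, double tol = 1e-3) {
  const int n = (int)idx.size();
  std::vector<double> alpha(n, 0.0), qii(n);
  std::vector<int> order(n);
  std::fill(w.begin(), w.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    order[i] = i;
    double s = 0.0;
    const int r = idx[i];
    for (int j = 0; j < d; ++j) {
      const double v = buf[(size_t)j * n_total + r];
      s += v * v;
    }
    qii[i] = s > 0 ? s : 1.0;
  }
  unsigned int rng = 123456789u; // fixed-seed LCG: deterministic shuffles
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {
      rng = rng * 1103515245u + 12345u;
      const int j = (int)((rng >> 8) % (unsigned)(i + 1));
      std::swap(order[i], order[j]);
    }
    double max_pg = 0.0;
    for (int oi = 0; oi < n; ++oi) {
      const int i = order[oi];
      const int r = idx[i];
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * buf[(size_t)j * n_total + r];
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (PG != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        if (a_new != a_old) {
          const double delta = (a_new - a_old) * y[i];
          for (int j = 0; j < d; ++j) w[j] += delta * buf[(size_t)j * n_total + r];
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
}

// PyMVPA-style C scaling: C = c_base / mean Euclidean norm of the training
// feature vectors (bias column excluded). Degenerate all-zero training
// features fall back to C = c_base.
static double scaled_C(const double *buf, int n_total, int d_feat,
                       const std::vector<int> &idx, double c_base) {
  double mean_norm = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) {
    double s = 0.0;
    const int r = idx[i];
    for (int j = 0; j < d_feat; ++j) {
      const double v = buf[(size_t)j * n_total + r];
      s += v * v;
    }
    mean_norm += std::sqrt(s);
  }
  mean_norm /= (double)idx.size();
  if (mean_norm < 1e-12) return c_base;
  return c_base / mean_norm;
}

// One-vs-one multiclass train + predict on a feature buffer. Classes are the
// sorted unique training labels; ties in voting go to the lowest class label.
// Returns predicted labels for the test rows.
static void ovo_train_predict(const double *buf, int n_total, int d,
                              const std::vector<int> &train_idx,
                              const std::vector<int> &train_lab,
                              const std::vector<int> &test_idx,
                              double c_base, std::vector<int> &pred) {
  std::vector<int> classes(train_lab);
  std::sort(classes.begin(), classes.end());
  classes.erase(std::unique(classes.begin(), classes.end()), classes.end());
  const int K = (int)classes.size();
  const int n_test = (int)test_idx.size();
  pred.assign(n_test, classes[0]);
  if (K < 2) return;
  const double C = scaled_C(buf, n_total, d - 1, train_idx, c_base);
  std::vector<std::vector<int> > votes(n_test, std::vector<int>(K, 0));
  std::vector<double> w((size_t)d);
  std::vector<int> sub_idx;
  std::vector<double> sub_y;
  for (int a = 0; a < K; ++a) {
    for (int b = a + 1; b < K; ++b) {
      sub_idx.clear();
      sub_y.clear();
      for (size_t i = 0; i < train_idx.size(); ++i) {
        if (train_lab[i] == classes[a]) {
          sub_idx.push_back(train_idx[i]);
          sub_y.push_back(1.0);
        } else if (train_lab[i] == classes[b]) {
          sub_idx.push_back(train_idx[i]);
          sub_y.push_back(-1.0);
        }
      }
      dcd_train(buf, n_total, d, sub_idx, sub_y, C, w);
      for (int t = 0; t < n_test; ++t) {
        const int r = test_idx[t];
        double s = 0.0;
        for (int j = 0; j < d; ++j) s += w[j] * buf[(size_t)j * n_total + r];
        // score == 0 resolves to the lower class index (deterministic)
        if (s >= 0.0) votes[t][a] += 1; else votes[t][b] += 1;
      }
    }
  }
  for (int t = 0; t < n_test; ++t) {
    int best = 0;
    for (int k = 1; k < K; ++k)
      if (votes[t][k] > votes[t][best]) best = k;
    pred[t] = classes[best];
  }
}

// [[Rcpp::export(name = ".svm_train_predict_cpp")]]
IntegerVector svm_train_predict_cpp(NumericMatrix X_train, IntegerVector y_train,
                                    NumericMatrix X_test, double c_base) {
  const int n_tr = X_train.nrow(), n_te = X_test.nrow(), d_feat = X_train.ncol();
  const int n = n_tr + n_te, d = d_feat + 1;
  std::vector<double> buf((size_t)n * d, 0.0);
  for (int j = 0; j < d_feat; ++j) {
    for (int i = 0; i < n_tr; ++i) buf[(size_t)j * n + i] = X_train(i, j);
    for (int i = 0; i < n_te; ++i) buf[(size_t)j * n + n_tr + i] = X_test(i, j);
  }
  for (int i = 0; i < n; ++i) buf[(size_t)d_feat * n + i] = 1.0; // bias column
  std::vector<int> train_idx(n_tr), test_idx(n_te), train_lab(n_tr);
  for (int i = 0; i < n_tr; ++i) { train_idx[i] = i; train_lab[i] = y_train[i]; }
  for (int i = 0; i < n_te; ++i) test_idx[i] = n_tr + i;
  std::vector<int> pred;
  ovo_train_predict(&buf[0], n, d, train_idx, train_lab, test_idx, c_base, pred);
  return wrap(pred);
}

// Searchlight kernel: for every center (a neighborhood = 1-based column
// indices into X), every labeling (column of `labels`), and every
// cross-validation split, train the one-vs-one linear C-SVM on the training
// rows and score the test rows; store the split-mean accuracy.
//
// X: samples x voxels; labels: samples x n_labelings integer class labels;
// splits_by_labeling: list of length n_labelings, each a list of
// list(train=IntegerVector, test=IntegerVector) with 1-based rows (the
// cross-validation scheme may depend on the labeling, e.g. when
// leave-two-identities-out splits are rebuilt from permuted class labels).
// Returns centers x n_labelings accuracy matrix.
// [[Rcpp::export(name = ".searchlight_accuracy_cpp")]]
NumericMatrix searchlight_accuracy_cpp(NumericMatrix X, List neighborhoods,
                                       IntegerMatrix labels,
                                       List splits_by_labeling,
                                       double c_base) {
  const int n = X.nrow();
  const int n_centers = neighborhoods.size();
  const int L = labels.ncol();
  if (labels.nrow() != n) stop("labels must have one row per sample");
  if (splits_by_labeling.size() != L)
    stop("need one split list per labeling");
  NumericMatrix out(n_centers, L);

  std::vector<std::vector<std::vector<int> > > split_train(L), split_test(L);
  for (int l = 0; l < L; ++l) {
    List splits = splits_by_labeling[l];
    const int S = splits.size();
    split_train[l].resize(S);
    split_test[l].resize(S);
    for (int s = 0; s < S; ++s) {
      List sp = splits[s];
      IntegerVector tr = sp["train"], te = sp["test"];
      split_train[l][s].assign(tr.begin(), tr.end());
      split_test[l][s].assign(te.begin(), te.end());
      for (size_t i = 0; i < split_train[l][s].size(); ++i) split_train[l][s][i] -= 1;
      for (size_t i = 0; i < split_test[l][s].size(); ++i) split_test[l][s][i] -= 1;
    }
  }

  std::vector<double> buf;
  std::vector<int> pred, train_lab;
  for (int c = 0; c < n_centers; ++c) {
    IntegerVector nb = neighborhoods[c];
    const int d_feat = nb.size(), d = d_feat + 1;
    buf.assign((size_t)n * d, 0.0);
    for (int j = 0; j < d_feat; ++j) {
      const int col = nb[j] - 1;
      for (int i = 0; i < n; ++i) buf[(size_t)j * n + i] = X(i, col);
    }
    for (int i = 0; i < n; ++i) buf[(size_t)d_feat * n + i] = 1.0;
    for (int l = 0; l < L; ++l) {
      double acc_sum = 0.0;
      const int S = (int)split_train[l].size();
      for (int s = 0; s < S; ++s) {
        const std::vector<int> &tr = split_train[l][s];
        const std::vector<int> &te = split_test[l][s];
        train_lab.resize(tr.size());
        for (size_t i = 0; i < tr.size(); ++i) train_lab[i] = labels(tr[i], l);
        ovo_train_predict(&buf[0], n, d, tr, train_lab, te, c_base, pred);
        int correct = 0;
        for (size_t i = 0; i < te.size(); ++i)
          if (pred[i] == labels(te[i], l)) ++correct;
        acc_sum += (double)correct / (double)te.size();
      }
      out(c, l) = acc_sum / (double)S;
    }
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
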