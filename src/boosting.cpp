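// Sparse coordinate-descent boosting for temporal response functions.
// The kernel (bands x lags) starts at zero; each iteration applies a
// +-step update to the cell that most reduces the training L1 error and
// training stops when the validation L1 error stops improving (the kernel
// at the validation minimum is returned). The candidate scan walks
// contiguous time runs of the training set so the shifted predictor and
// the residual are read sequentially.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// prediction of one electrode's EEG from the kernel: y_hat[t] =
// sum_b sum_i K(b,i) * P(b, t - lag[i]) with zero outside the record.
// [[Rcpp::export]]
arma::vec trf_predict_cpp(const arma::mat& P, const arma::mat& K,
                          const arma::ivec& lag_samp) {
  const int nt = P.n_cols, nb = P.n_rows, nl = lag_samp.n_elem;
  vec y(nt, fill::zeros);
  for (int b = 0; b < nb; ++b) {
    for (int i = 0; i < nl; ++i) {
      const double w = K(b, i);
      if (w == 0.0) continue;
      const int l = lag_samp[i];
      const int t0 = std::max(0, l), t1 = std::min(nt, nt + l);
      for (int t = t0; t < t1; ++t) y[t] += w * P(b, t - l);
    }
  }
  return y;
}

// collapse a sorted index vector into [start, end) runs
static std::vector<std::pair<int,int>> index_runs(const arma::uvec& idx) {
  std::vector<std::pair<int,int>> runs;
  if (idx.n_elem == 0) return runs;
  int a = idx[0], prev = idx[0];
  for (uword k = 1; k < idx.n_elem; ++k) {
    if ((int)idx[k] != prev + 1) {
      runs.emplace_back(a, prev + 1);
      a = idx[k];
    }
    prev = idx[k];
  }
  runs.emplace_back(a, prev + 1);
  return runs;
}

// [[Rcpp::export]]
arma::mat boost_trf_cpp(const arma::mat& P, const arma::vec& y,
                        const arma::ivec& lag_samp,
                        const arma::uvec& idx_fit, const arma::uvec& idx_val,
                        double step, int max_iter, int patience) {
  const int nt = P.n_cols, nb = P.n_rows, nl = lag_samp.n_elem;
  if ((int)y.n_elem != nt) Rcpp::stop("predictor/EEG length mismatch");
  if (max_iter < 1) Rcpp::stop("at least one boosting iteration required");

  const mat Pt = P.t();                  // time-contiguous per band
  mat K(nb, nl, fill::zeros), bestK = K;
  vec resid = y;
  const double* r = resid.memptr();
  const auto fit_runs = index_runs(idx_fit);

  auto err_on = [&](const uvec& idx) {
    double e = 0.0;
    for (uword k = 0; k < idx.n_elem; ++k) e += std::fabs(resid[idx[k]]);
    return e;
  };

  double fit_err = err_on(idx_fit);
  double best_val = err_on(idx_val);
  int wait = 0;

  for (int iter = 0; iter < max_iter; ++iter) {
    double best_err = fit_err - 1e-12;   // require strict descent
    int best_b = -1, best_i = -1;
    double best_sign = 0.0;
    for (int b = 0; b < nb; ++b) {
      const double* pb = Pt.colptr(b);
      for (int i = 0; i < nl; ++i) {
        const int l = lag_samp[i];
        double ep = 0.0, em = 0.0;
        for (const auto& run : fit_runs) {
          int t0 = std::max(run.first, l);
          int t1 = std::min(run.second, nt + l);
          // samples in the run whose source falls outside the record keep
          // their residual unchanged
          for (int t = run.first; t < std::min(t0, run.second); ++t) {
            const double a = std::fabs(r[t]); ep += a; em += a;
          }
          for (int t = std::max(t1, run.first); t < run.second; ++t) {
            const double a = std::fabs(r[t]); ep += a; em += a;
          }
          const double* ps = pb - l;
          for (int t = t0; t < t1; ++t) {
            const double d = step * ps[t];
            ep += std::fabs(r[t] - d);
            em += std::fabs(r[t] + d);
          }
        }
        if (ep < best_err) { best_err = ep; best_b = b; best_i = i; best_sign = 1.0; }
        if (em < best_err) { best_err = em; best_b = b; best_i = i; best_sign = -1.0; }
      }
    }
    if (best_b < 0) break;               // training error cannot be reduced
    const double w = best_sign * step;
    K(best_b, best_i) += w;
    const int l = lag_samp[best_i];
    const int t0 = std::max(0, l), t1 = std::min(nt, nt + l);
    const double* pb = Pt.colptr(best_b) - l;
    for (int t = t0; t < t1; ++t) resid[t] -= w * pb[t];
    fit_err = best_err;

    const double val_err = err_on(idx_val);
    if (val_err < best_val - 1e-12) {
      best_val = val_err;
      bestK = K;
      wait = 0;
    } else if (++wait > patience) break;
  }
  return bestK;
}
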