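// Numeric kernels for the voxelwise engines.
// Matrices are (time x voxel); one column per in-mask voxel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Detrended fluctuation analysis (order 1), all voxels at once.
// x: (n x V) series matrix; scales: window lengths.
// Returns (n_scales x V) matrix of RMS fluctuations F(s).
// [[Rcpp::export]]
arma::mat cpp_dfa_fluct(const arma::mat& x, const arma::ivec& scales) {
  const arma::uword n = x.n_rows, V = x.n_cols, S = scales.n_elem;
  arma::mat f(S, V, arma::fill::zeros);
  arma::mat prof(n, V);
  for (arma::uword v = 0; v < V; ++v) {
    double mu = arma::mean(x.col(v));
    double acc = 0.0;
    for (arma::uword t = 0; t < n; ++t) {
      acc += x(t, v) - mu;
      prof(t, v) = acc;
    }
  }
  for (arma::uword si = 0; si < S; ++si) {
    const arma::uword s = (arma::uword)scales(si);
    const arma::uword m = n / s;  // non-overlapping windows, remainder dropped
    const double sd = (double)s;
    const double Sx = sd * (sd + 1.0) / 2.0;
    const double Sxx = sd * (sd + 1.0) * (2.0 * sd + 1.0) / 6.0;
    const double det = sd * Sxx - Sx * Sx;
    for (arma::uword v = 0; v < V; ++v) {
      double rss = 0.0;
      for (arma::uword w = 0; w < m; ++w) {
        const arma::uword off = w * s;
        double Sy = 0.0, Sxy = 0.0, Syy = 0.0;
        for (arma::uword t = 0; t < s; ++t) {
          const double y = prof(off + t, v);
          Sy += y;
          Sxy += (t + 1.0) * y;
          Syy += y * y;
        }
        const double b = (sd * Sxy - Sx * Sy) / det;
        const double a = (Sy - b * Sx) / sd;
        double r = Syy - a * Sy - b * Sxy;
        if (r < 0.0) r = 0.0;  // guard rounding
        rss += r;
      }
      f(si, v) = std::sqrt(rss / (double)(m * s));
    }
  }
  return f;
}

// Column-wise midranks.
// [[Rcpp::export]]
arma::mat cpp_midranks(const arma::mat& x) {
  const arma::uword n = x.n_rows, V = x.n_cols;
  arma::mat r(n, V);
  std::vector<std::pair<double, arma::uword>> a(n);
  for (arma::uword v = 0; v < V; ++v) {
    const double* col = x.colptr(v);
    for (arma::uword i = 0; i < n; ++i) a[i] = {col[i], i};
    std::sort(a.begin(), a.end());
    arma::uword i = 0;
    while (i < n) {
      arma::uword j = i;
      while (j + 1 < n && a[j + 1].first == a[i].first) ++j;
      const double mid = 0.5 * ((double)i + (double)j) + 1.0;
      for (arma::uword k = i; k <= j; ++k) r(a[k].second, v) = mid;
      i = j + 1;
    }
  }
  return r;
}

// Kendall's coefficient of concordance over each voxel's neighborhood.
// ranks: (n x V) midrank matrix; nbr: (V x Kmax) 0-based column indices of the
// in-mask neighbors of each voxel (including itself), -1 padding.
// W = 12 * sum_t (R_t - mean)^2 / (K^2 (n^3 - n)), no tie correction.
// [[Rcpp::export]]
arma::vec cpp_kendall_w(const arma::mat& ranks, const arma::imat& nbr) {
  const arma::uword n = ranks.n_rows, V = nbr.n_rows, Kmax = nbr.n_cols;
  arma::vec w(V);
  std::vector<double> rsum(n);
  const double denom_t = (double)n * ((double)n * (double)n - 1.0);
  for (arma::uword v = 0; v < V; ++v) {
    std::fill(rsum.begin(), rsum.end(), 0.0);
    double K = 0.0;
    for (arma::uword k = 0; k < Kmax; ++k) {
      const int j = nbr(v, k);
      if (j < 0) continue;
      ++K;
      const double* col = ranks.colptr((arma::uword)j);
      for (arma::uword t = 0; t < n; ++t) rsum[t] += col[t];
    }
    const double mean = K * (n + 1.0) / 2.0;
    double ss = 0.0;
    for (arma::uword t = 0; t < n; ++t) {
      const double d = rsum[t] - mean;
      ss += d * d;
    }
    w(v) = 12.0 * ss / (K * K * denom_t);
  }
  return w;
}

// Pearson correlation of every column of y with `ref` at each integer lag.
// Positive lag l compares y[(1+l)..n] with ref[1..(n-l)] (voxel delayed).
// Returns (n_lags x V); columns with zero variance in any segment give NaN.
// [[Rcpp::export]]
arma::mat cpp_lag_corr(const arma::mat& y, const arma::vec& ref,
                       const arma::ivec& lags) {
  const arma::uword n = y.n_rows, V = y.n_cols, L = lags.n_elem;
  arma::mat out(L, V);
  for (arma::uword li = 0; li < L; ++li) {
    const int l = lags(li);
    const arma::uword len = n - (arma::uword)std::abs(l);
    const arma::uword ya = l >= 0 ? (arma::uword)l : 0;
    const arma::uword ra = l >= 0 ? 0 : (arma::uword)(-l);
    arma::vec r = ref.subvec(ra, ra + len - 1);
    const double rmean = arma::mean(r);
    r -= rmean;
    const double rss = arma::dot(r, r);
    for (arma::uword v = 0; v < V; ++v) {
      const double* col = y.colptr(v) + ya;
      double s = 0.0, ss = 0.0, sxy = 0.0;
      for (arma::uword t = 0; t < len; ++t) {
        const double x = col[t];
        s += x;
        ss += x * x;
        sxy += x * r(t);
      }
      const double xss = ss - s * s / (double)len;
      const double denom = std::sqrt(xss * rss);
      out(li, v) = denom > 0 ? sxy / denom : arma::datum::nan;
    }
  }
  return out;
}

// Index (1-based) of the first maximum of each column; 0 when any entry is NaN.
// [[Rcpp::export]]
arma::ivec cpp_col_argmax(const arma::mat& x) {
  const arma::uword R = x.n_rows, V = x.n_cols;
  arma::ivec out(V);
  for (arma::uword v = 0; v < V; ++v) {
    const double* col = x.colptr(v);
    double best = col[0];
    arma::uword bi = 0;
    bool bad = std::isnan(col[0]);
    for (arma::uword i = 1; i < R && !bad; ++i) {
      if (std::isnan(col[i])) { bad = true; break; }
      if (col[i] > best) { best = col[i]; bi = i; }
    }
    out(v) = bad ? 0 : (int)(bi + 1);
  }
  return out;
}
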