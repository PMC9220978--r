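# Shared fixtures and independent oracle implementations.
# Oracles are deliberately naive (loops, exhaustive scans) and never share
# code with the package internals they check.

# wrap a (time x voxel) matrix as a single-row bold_series grid
series_from_cols <- function(y, tr = 1, nx = NULL) {
  v <- ncol(y)
  if (is.null(nx)) nx <- v
  arr <- array(0, dim = c(nx, 1, 1, nrow(y)))
  for (j in seq_len(v)) arr[j, 1, 1, ] <- y[, j]
  bold_series(arr, tr = tr)
}

# a small 3D grid series filled with N(0,1) noise
noise_series <- function(dim3 = c(6, 6, 6), n = 100, tr = 1, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(prod(dim3) * n), dim = c(dim3, n))
  bold_series(arr, tr = tr)
}

tiny_phantom_config <- function(seed = 7, ...) {
  phantom_config(grid_shape = c(8L, 8L, 8L), seed = seed, ...)
}

# pure tone at DFT bin k whose least-squares line fit is exactly zero, so
# linear detrending leaves it untouched and spectral expectations are exact
slopefree_tone <- function(n, k, amp = 1) {
  t0 <- 0:(n - 1)
  s1 <- sin(2 * pi * k * t0 / n)
  s2 <- cos(2 * pi * k * t0 / n)
  b1 <- stats::coef(stats::lm(s1 ~ t0))[2]
  b2 <- stats::coef(stats::lm(s2 ~ t0))[2]
  phi <- atan2(-b1, b2)
  x <- amp * (cos(phi) * s1 + sin(phi) * s2)
  stopifnot(abs(stats::coef(stats::lm(x ~ t0))[2]) < 1e-10)
  x
}

# --- oracles -------------------------------------------------------------

# ALFF/fALFF by direct DFT summation, one series at a time
oracle_amplitudes <- function(x) {
  n <- length(x)
  tt <- seq_len(n)
  x <- stats::lm(x ~ tt)$residuals
  k <- seq_len(floor(n / 2))
  a <- numeric(length(k))
  for (i in seq_along(k)) {
    w <- 2 * pi * k[i] * (0:(n - 1)) / n
    a[i] <- 2 * sqrt(sum(x * cos(w))^2 + sum(x * sin(w))^2) / n
  }
  a
}

oracle_alff <- function(x, tr, band) {
  a <- oracle_amplitudes(x)
  bins <- band_bin_indices(length(x), tr, band)
  mean(a[bins])
}

oracle_falff <- function(x, tr, band) {
  a <- oracle_amplitudes(x)
  bins <- band_bin_indices(length(x), tr, band)
  if (sum(a) == 0) return(0)
  sum(a[bins]) / sum(a)
}

# Kendall's W from the raw formula, K series as columns
oracle_kendall_w <- function(series_mat) {
  n <- nrow(series_mat)
  k <- ncol(series_mat)
  r <- apply(series_mat, 2, rank)
  rs <- rowSums(r)
  12 * sum((rs - mean(rs))^2) / (k^2 * (n^3 - n))
}

# exhaustive-lag TSA scan with the package's stated tie-break policy
oracle_tsa <- function(x, ref, max_lag) {
  n <- length(x)
  lags <- (-max_lag):max_lag
  lags <- lags[order(abs(lags), lags)]
  best_r <- -Inf
  best_l <- NA_real_
  for (l in lags) {
    if (l >= 0) {
      r <- suppressWarnings(cor(x[(1 + l):n], ref[1:(n - l)]))
    } else {
      r <- suppressWarnings(cor(x[1:(n + l)], ref[(1 - l):n]))
    }
    if (is.na(r)) return(NA_real_)
    if (r > best_r) {
      best_r <- r
      best_l <- l
    }
  }
  best_l
}

# AUROC by exhaustive pair counting (ties count one half)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# jackknife variance of the difference of paired AUCs
oracle_delong_jackknife_var <- function(sa, sb, labels) {
  n <- length(labels)
  d_full <- oracle_auc_pairs(sa, labels) - oracle_auc_pairs(sb, labels)
  d_i <- vapply(seq_len(n), function(i) {
    oracle_auc_pairs(sa[-i], labels[-i]) - oracle_auc_pairs(sb[-i], labels[-i])
  }, numeric(1))
  ps <- n * d_full - (n - 1) * d_i  # pseudovalues
  stats::var(ps) / n
}

# spectrally shaped noise with power ~ f^(1 - 2H) (independent of the phantom)
oracle_fgn_like <- function(n, h, seed) {
  set.seed(seed)
  kmax <- floor((n - 1) / 2)
  amp <- (seq_len(kmax))^((1 - 2 * h) / 2)
  ph <- runif(kmax, 0, 2 * pi)
  sp <- complex(length.out = n)
  sp[1 + seq_len(kmax)] <- amp * exp(1i * ph)
  sp[n + 1 - seq_len(kmax)] <- Conj(sp[1 + seq_len(kmax)])
  Re(stats::fft(sp, inverse = TRUE)) / n
}

# random feature table with the package's naming grammar
random_feature_table <- function(n, features = feature_names(), seed = 1,
                                 balance = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(features)), n, length(features))
  colnames(x) <- features
  lab <- rep(0L, n)
  lab[sample.int(n, round(balance * n))] <- 1L
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%04d", seq_len(n)), label = lab),
    tibble::as_tibble(x)
  )
}
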