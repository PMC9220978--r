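#' Discard initial volumes
#'
#' Drops the first `k` volumes of a series (scanner equilibration). With
#' TR = 1 s acquisitions of 405 volumes the conventional `k = 5` leaves 400.
#'
#' @param series A [bold_series].
#' @param k Number of leading volumes to drop (`0 <= k < t`).
#' @return A [bold_series] with `t - k` volumes.
#' @export
discard_initial_volumes <- function(series, k = 5L) {
  stopifnot(inherits(series, "bold_series"))
  k <- as.integer(k)
  t <- n_volumes(series)
  if (k < 0L) stop("k must be non-negative")
  if (k >= t) stop("cannot discard ", k, " of ", t, " volumes; the series would be empty")
  if (k == 0L) return(series)
  out <- series
  out$data <- series$data[, , , (k + 1L):t, drop = FALSE]
  out
}

#' Nuisance regressor table
#'
#' Named regressor columns (six motion parameters, white-matter mean, CSF
#' mean, ...), one row per retained volume. Stored as a plain numeric matrix
#' with column names.
#'
#' @param ... Named numeric vectors of equal length, or a single data frame /
#'   matrix with named columns.
#' @return A `nuisance_table` (numeric matrix).
#' @export
nuisance_table <- function(...) {
  args <- list(...)
  if (length(args) == 1L && (is.data.frame(args[[1]]) || is.matrix(args[[1]]))) {
    m <- as.matrix(args[[1]])
  } else {
    m <- do.call(cbind, args)
  }
  storage.mode(m) <- "double"
  if (is.null(colnames(m)) || any(colnames(m) == "")) {
    stop("every nuisance column must be named")
  }
  structure(m, class = c("nuisance_table", "matrix", "array"))
}

#' Drop the first k rows of a nuisance table
#'
#' Companion of [discard_initial_volumes()] so motion tables recorded for the
#' full acquisition can be aligned with the truncated series.
#'
#' @param nuisance A [nuisance_table] or matrix.
#' @param k Rows to drop.
#' @return The truncated table.
#' @export
discard_initial_rows <- function(nuisance, k = 5L) {
  k <- as.integer(k)
  if (k >= nrow(nuisance)) stop("cannot discard ", k, " of ", nrow(nuisance), " rows")
  if (k == 0L) return(nuisance)
  out <- nuisance[(k + 1L):nrow(nuisance), , drop = FALSE]
  class(out) <- class(nuisance)
  out
}

#' Read a whitespace-delimited nuisance table
#' @param path Text file, one column per regressor with a header row.
#' @return A [nuisance_table].
#' @export
read_nuisance <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  nuisance_table(df)
}

#' Write a nuisance table as whitespace-delimited text
#' @param nuisance A [nuisance_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nuisance <- function(nuisance, path) {
  utils::write.table(unclass(nuisance), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Global mean signal
#'
#' Mean time series over the brain mask, excluding the tumor subregions when
#' an `roi_set` is given, so that the measured lesion signal is not regressed
#' out of itself.
#'
#' @param series A [bold_series].
#' @param exclude Optional [roi_set] to exclude from the average.
#' @return Numeric vector of length `t`.
#' @export
global_signal <- function(series, exclude = NULL) {
  mask <- series$brain_mask
  if (!is.null(exclude)) mask <- mask & !roi_union(exclude)
  if (!any(mask)) stop("global-signal mask is empty")
  rowMeans(series_matrix(series, mask))
}

#' Regress nuisance covariates out of every voxel
#'
#' Each in-mask voxel time series is replaced by its least-squares residual
#' against an intercept, the nuisance columns, and (optionally) the global
#' mean signal. Residuals are orthogonal to every regressor.
#'
#' @param series A [bold_series].
#' @param nuisance A [nuisance_table] with one row per volume.
#' @param include_global Add the global mean series as a regressor (GSR)?
#' @param global_exclude Optional [roi_set] excluded from the global mean.
#' @return A [bold_series] of residuals.
#' @export
regress_nuisance <- function(series, nuisance, include_global = FALSE,
                             global_exclude = NULL) {
  stopifnot(inherits(series, "bold_series"))
  t <- n_volumes(series)
  x <- unclass(nuisance)
  if (nrow(x) != t) {
    stop("nuisance table has ", nrow(x), " rows but the series has ", t, " volumes")
  }
  design <- cbind(intercept = rep(1, t), x)
  if (include_global) {
    design <- cbind(design, global = global_signal(series, exclude = global_exclude))
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop(
      "nuisance design is rank-deficient; offending column(s): ",
      paste(bad, collapse = ", ")
    )
  }
  y <- series_matrix(series)
  res <- qr.resid(qrd, y)
  series_from_matrix(series, res)
}

#' Remove a per-voxel linear trend
#'
#' Least-squares line (intercept + slope) removed from every in-mask voxel.
#'
#' @param series A [bold_series].
#' @return A detrended [bold_series].
#' @export
detrend_linear <- function(series) {
  y <- series_matrix(series)
  series_from_matrix(series, detrend_matrix(y))
}

detrend_matrix <- function(y) {
  t <- nrow(y)
  x <- cbind(1, seq_len(t))
  qr.resid(qr(x), y)
}

# frequency-domain mask for a band over the full (two-sided) DFT of length n
band_fft_mask <- function(n, tr, band) {
  keep_pos <- band_bin_indices(n, tr, band)
  m <- rep(FALSE, n)
  m[keep_pos + 1L] <- TRUE          # positive frequencies (1-based; index 1 = DC)
  m[n + 1L - keep_pos] <- TRUE      # conjugate (negative) frequencies
  m
}

# inverse DFT of conjugate-symmetric spectra, two real columns per complex
# transform
inv_real_mvfft <- function(sp) {
  n <- nrow(sp)
  v <- ncol(sp)
  out <- matrix(0, n, v)
  h <- seq_len(v %/% 2) * 2L
  if (length(h)) {
    z <- stats::mvfft(sp[, h - 1L, drop = FALSE] + 1i * sp[, h, drop = FALSE],
                      inverse = TRUE) / n
    out[, h - 1L] <- Re(z)
    out[, h] <- Im(z)
  }
  if (v %% 2 == 1L) {
    out[, v] <- Re(stats::mvfft(sp[, v, drop = FALSE], inverse = TRUE)) / n
  }
  out
}

# cached cosine/sine synthesis basis for the bins of a band: the ideal filter
# output is basis %*% rbind(Re X, Im X) for bins strictly below Nyquist
.basis_cache <- new.env(parent = emptyenv())
band_synthesis_basis <- function(n, tr, band) {
  key <- paste(n, tr, band$name, band$low, band$high, band$closed_high, sep = "|")
  if (!exists(key, envir = .basis_cache)) {
    bins <- band_bin_indices(n, tr, band)
    ang <- outer(0:(n - 1), bins) * (2 * pi / n)
    assign(key, cbind(cos(ang), -sin(ang)) * (2 / n), envir = .basis_cache)
  }
  get(key, envir = .basis_cache)
}

bandpass_matrix <- function(y, tr, band) {
  n <- nrow(y)
  keep <- band_fft_mask(n, tr, band)
  sp <- stats::mvfft(y)
  sp[!keep, ] <- 0
  inv_real_mvfft(sp)
}

#' Ideal band-pass filter
#'
#' Per voxel: a frequency-domain (ideal) filter retaining exactly the DFT
#' bins whose frequencies lie inside `band`. The DC component and all
#' out-of-band content — in particular the bulk of any constant offset or
#' linear drift — are annihilated, which is what makes the operator an exact
#' projection: it is linear and idempotent, passes exact-bin tones untouched
#' and rejects out-of-band tones completely. Algebraically the mask equals an
#' ideal filter composed with a linear detrend whose trend basis has been
#' orthogonalized against the passband. The pipeline additionally applies an
#' explicit least-squares detrend ([detrend_linear()]) to every stream before
#' filtering, which also removes the small in-band leakage of linear drifts.
#'
#' @param series A [bold_series].
#' @param band A [frequency_band]; must lie below Nyquist for the series TR.
#' @return A filtered [bold_series].
#' @export
bandpass <- function(series, band) {
  stopifnot(inherits(series, "bold_series"), inherits(band, "frequency_band"))
  check_band_valid(band, series$tr)
  y <- series_matrix(series)
  series_from_matrix(series, bandpass_matrix(y, series$tr, band))
}

# 1D discrete Gaussian kernel, sd in voxels
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# convolution matrix with edge renormalization (mass-preserving in the
# interior, constant-preserving at the boundary)
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    w <- kernel[ok]
    m[i, j[ok]] <- w / sum(w)
  }
  m
}

apply_along_axis <- function(arr4, axis, mat) {
  # multiplies volumes by `mat` along one spatial axis: out = mat %*% arr(axis-first)
  d <- dim(arr4)
  perm <- c(axis, setdiff(1:4, axis))
  a <- aperm(arr4, perm)
  da <- dim(a)
  a <- matrix(a, da[1])
  a <- mat %*% a
  a <- array(a, da)
  aperm(a, order(perm))
}

#' Isotropic Gaussian spatial smoothing
#'
#' Each volume is convolved with a separable Gaussian of the requested full
#' width at half maximum (FWHM), using the voxel sizes from the affine;
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis in mm. Edge kernels are
#' renormalized, so constant volumes are unchanged and interior mass is
#' preserved. `fwhm_mm = 0` is the identity.
#'
#' @param series A [bold_series].
#' @param fwhm_mm Kernel FWHM in mm (>= 0); the conventional choice is 6.
#' @return A smoothed [bold_series].
#' @export
smooth_gaussian <- function(series, fwhm_mm = 6) {
  stopifnot(inherits(series, "bold_series"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(series)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vox <- voxel_sizes_mm(series)
  d <- dim(series$data)
  out <- series$data
  for (axis in 1:3) {
    kern <- gaussian_kernel_1d(sigma_mm / vox[axis])
    if (length(kern) > 1L) {
      out <- apply_along_axis(out, axis, conv_matrix(d[axis], kern))
    }
  }
  series2 <- series
  series2$data <- out
  series2
}
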