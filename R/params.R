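#' Parameter variant
#'
#' One of the 14 admissible regional-parameter variants: ALFF and fALFF
#' (always computed on smoothed data), ReHo (always unsmoothed), and the Hurst
#' exponent (HE) and time-shift analysis (TSA) lag in smoothed and unsmoothed
#' flavours, each with and without global signal regression (GSR).
#'
#' @param base One of `"alff"`, `"falff"`, `"reho"`, `"he"`, `"tsa"`.
#' @param smoothed Logical; fixed `TRUE` for ALFF/fALFF, fixed `FALSE` for
#'   ReHo, free for HE/TSA.
#' @param global_regressed Logical; was the global mean signal regressed out?
#' @return A `parameter_variant` object.
#' @export
parameter_variant <- function(base, smoothed, global_regressed) {
  base <- match.arg(base, c("alff", "falff", "reho", "he", "tsa"))
  smoothed <- isTRUE(smoothed)
  if (base %in% c("alff", "falff") && !smoothed) {
    stop(base, " is defined on smoothed data only")
  }
  if (base == "reho" && smoothed) {
    stop("reho is defined on unsmoothed data only")
  }
  structure(
    list(base = base, smoothed = smoothed, global_regressed = isTRUE(global_regressed)),
    class = "parameter_variant"
  )
}

#' Variant label used in feature names
#'
#' `<base>_<s|ns>_<gsr|nogsr>`, e.g. `"tsa_ns_gsr"`.
#'
#' @param variant A [parameter_variant].
#' @return Character scalar.
#' @export
variant_label <- function(variant) {
  sprintf(
    "%s_%s_%s", variant$base,
    if (variant$smoothed) "s" else "ns",
    if (variant$global_regressed) "gsr" else "nogsr"
  )
}

#' @export
print.parameter_variant <- function(x, ...) {
  cat("<parameter_variant>", variant_label(x), "\n")
  invisible(x)
}

#' The 14 admissible parameter variants, in canonical order
#'
#' Order is variant-major and deterministic: ALFF, fALFF, ReHo, HE smoothed,
#' HE unsmoothed, TSA smoothed, TSA unsmoothed; within each, no-GSR before
#' GSR.
#'
#' @param bases Subset of bases to keep (default all five).
#' @return List of [parameter_variant] objects (14 at defaults).
#' @export
admissible_variants <- function(bases = c("alff", "falff", "reho", "he", "tsa")) {
  bases <- match.arg(bases, several.ok = TRUE)
  out <- list()
  for (b in bases) {
    smooth_opts <- switch(b,
      alff = TRUE, falff = TRUE, reho = FALSE,
      he = c(TRUE, FALSE), tsa = c(TRUE, FALSE)
    )
    for (sm in smooth_opts) {
      for (g in c(FALSE, TRUE)) {
        out[[length(out) + 1L]] <- parameter_variant(b, sm, g)
      }
    }
  }
  out
}

#' Voxelwise parameter map
#'
#' A 3D map of one regional parameter for one (variant, band) cell. Values are
#' `NA` outside the brain mask and for degenerate voxels (the missing code);
#' the count of degenerate in-mask voxels is kept in `n_missing`.
#'
#' @param values 3D numeric array.
#' @param variant A [parameter_variant].
#' @param band A [frequency_band].
#' @param n_missing Count of in-mask voxels flagged missing.
#' @return A `parameter_map` object.
#' @export
parameter_map <- function(values, variant, band, n_missing = 0L) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  structure(
    list(values = values, variant = variant, band = band,
         n_missing = as.integer(n_missing)),
    class = "parameter_map"
  )
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf(
    "<parameter_map> %s @ %s: %s, %d missing\n",
    variant_label(x$variant), x$band$name,
    paste(dim(x$values), collapse = "x"), x$n_missing
  ))
  invisible(x)
}

map_from_values <- function(series, vals, variant, band) {
  arr <- array(NA_real_, dim = dim(series$data)[1:3])
  arr[series$brain_mask] <- vals
  parameter_map(arr, variant, band, n_missing = sum(is.na(vals)))
}

#' Write a parameter map as NIfTI with a JSON sidecar
#' @param map A [parameter_map].
#' @param path Output NIfTI path; the sidecar is written next to it.
#' @param voxel_size_mm Voxel sizes for the header.
#' @return `path`, invisibly.
#' @export
write_parameter_map <- function(map, path, voxel_size_mm = c(3, 3, 3)) {
  img <- RNifti::asNifti(map$values, pixdim = c(voxel_size_mm, 1))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(variant = variant_label(map$variant),
         band = list(low = map$band$low, high = map$band$high, name = map$band$name),
         n_missing = map$n_missing),
    side, auto_unbox = TRUE
  )
  invisible(path)
}

## ---- matrix-level engines (time x voxel) --------------------------------

# one-sided amplitude spectrum a(f) = 2|X(f)| / N per voxel, DC excluded
amplitude_spectrum <- function(y) {
  n <- nrow(y)
  sp <- stats::mvfft(detrend_matrix(y))
  k <- seq_len(floor(n / 2))
  2 * Mod(sp[k + 1L, , drop = FALSE]) / n
}

alff_matrix <- function(y, tr, band) {
  n <- nrow(y)
  bins <- band_bin_indices(n, tr, band)
  if (length(bins) < 2L) {
    stop("band '", band$name, "' covers ", length(bins),
         " DFT bin(s) at n = ", n, ", tr = ", tr, "; need at least 2")
  }
  a <- amplitude_spectrum(y)
  colMeans(a[bins, , drop = FALSE])
}

falff_matrix <- function(y, tr, band) {
  n <- nrow(y)
  bins <- band_bin_indices(n, tr, band)
  if (length(bins) < 2L) {
    stop("band '", band$name, "' covers ", length(bins),
         " DFT bin(s) at n = ", n, ", tr = ", tr, "; need at least 2")
  }
  a <- amplitude_spectrum(y)
  num <- colSums(a[bins, , drop = FALSE])
  den <- colSums(a)
  out <- ifelse(den > 0, num / den, 0)  # 0/0 -> 0
  out
}

# neighborhood offsets for ReHo: 7 (faces), 19 (faces+edges), 27 (full cube)
neighborhood_offsets <- function(k = 27L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(g))
  switch(as.character(k),
    "7"  = g[s <= 1, , drop = FALSE],
    "19" = g[s <= 2, , drop = FALSE],
    "27" = g,
    stop("neighborhood must be one of 7, 19, 27")
  )
}

# V x K matrix of 0-based in-mask neighbor column indices (-1 = absent)
neighbor_index_matrix <- function(mask, k = 27L) {
  off <- neighborhood_offsets(k)
  d <- dim(mask)
  colidx <- array(-1L, dim = d)
  colidx[mask] <- seq_len(sum(mask)) - 1L
  vox <- which(mask, arr.ind = TRUE)
  v <- nrow(vox)
  nbr <- matrix(-1L, v, nrow(off))
  for (j in seq_len(nrow(off))) {
    p <- sweep(vox, 2, off[j, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] &
      p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    lin <- rep(-1L, v)
    lin[ok] <- colidx[p[ok, , drop = FALSE]]
    nbr[, j] <- lin
  }
  nbr
}

reho_matrix <- function(y, nbr) {
  if (nrow(y) < 3L) stop("ReHo needs at least 3 time points")
  ranks <- cpp_midranks(y)
  cpp_kendall_w(ranks, nbr)
}

default_dfa_scales <- function(n, n_scales = 8L) {
  s <- unique(round(exp(seq(log(4), log(n / 4), length.out = n_scales))))
  if (length(s) < 4L) stop("series too short for DFA: only ", length(s), " usable scales")
  as.integer(s)
}

hurst_matrix <- function(y, scales = NULL) {
  n <- nrow(y)
  if (is.null(scales)) scales <- default_dfa_scales(n)
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 4L) stop("DFA needs at least 4 scales")
  if (max(scales) > n / 4) stop("largest DFA scale exceeds n/4")
  if (min(scales) < 3L) stop("DFA scales must be >= 3")
  cm <- colMeans(y)
  degenerate <- colMeans(y^2) - cm^2 <= 1e-300
  f <- cpp_dfa_fluct(y, scales)
  lx <- cbind(1, log(scales))
  slope_row <- solve(crossprod(lx), t(lx))[2L, ]  # least-squares slope operator
  out <- rep(NA_real_, ncol(y))
  ok <- !degenerate & colSums(f <= 0) == 0
  if (any(ok)) {
    out[ok] <- as.vector(slope_row %*% log(f[, ok, drop = FALSE]))
  }
  out
}

# lag order implementing the tie-break: smallest |lag| first, negative before
# positive at equal magnitude
tsa_lag_order <- function(max_lag) {
  lags <- -max_lag:max_lag
  lags[order(abs(lags), lags)]
}

tsa_matrix <- function(y, reference, max_lag = 3L) {
  n <- nrow(y)
  if (length(reference) != n) stop("reference length must equal the series length")
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("max_lag must be >= 1")
  if (stats::sd(reference) == 0) return(rep(NA_real_, ncol(y)))
  lags <- tsa_lag_order(max_lag)
  r <- cpp_lag_corr(y, reference, as.integer(lags))
  best <- cpp_col_argmax(r)  # first max implements the tie-break order; 0 = NaN
  out <- rep(NA_real_, ncol(y))
  out[best > 0] <- lags[best[best > 0]]
  out
}

## ---- public voxel-map engines -------------------------------------------

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Per voxel: linear detrend, DFT, one-sided amplitude spectrum
#' `a(f) = 2|X(f)|/N`, then the mean of `a(f)` over the DFT bins inside
#' `band`. With the band mean (rather than sum) a pure tone of amplitude A at
#' one in-band bin gives ALFF = A / (number of in-band bins), and values are
#' comparable across bands of different widths.
#'
#' @param series A [bold_series]; conventionally nuisance-regressed and
#'   smoothed, but unfiltered (the band selection happens here).
#' @param band A [frequency_band] covering at least 2 DFT bins.
#' @param variant Optional [parameter_variant] tag for the output map.
#' @return A [parameter_map] in signal units (a.u.).
#' @export
compute_alff <- function(series, band,
                         variant = parameter_variant("alff", TRUE, FALSE)) {
  check_band_valid(band, series$tr)
  vals <- alff_matrix(series_matrix(series), series$tr, band)
  map_from_values(series, vals, variant, band)
}

#' Fractional ALFF (fALFF)
#'
#' Per voxel: the sum of the amplitude spectrum over the in-band bins divided
#' by the sum over all bins in (0, Nyquist]; 0/0 is defined as 0. Bounded in
#' \[0, 1\].
#'
#' @inheritParams compute_alff
#' @return A [parameter_map] of ratios in \[0, 1\].
#' @export
compute_falff <- function(series, band,
                          variant = parameter_variant("falff", TRUE, FALSE)) {
  check_band_valid(band, series$tr)
  vals <- falff_matrix(series_matrix(series), series$tr, band)
  map_from_values(series, vals, variant, band)
}

#' Regional homogeneity (ReHo)
#'
#' Kendall's coefficient of concordance W of the time-series ranks of each
#' voxel and its in-mask neighbors:
#' `W = 12 * sum_t (R_t - mean(R))^2 / (K^2 (n^3 - n))`
#' with midranks for ties and no tie correction. Edge voxels use the reduced
#' set of available in-mask neighbors.
#'
#' @param series A [bold_series]; conventionally nuisance-regressed,
#'   unsmoothed and band-filtered before calling.
#' @param neighborhood Cluster size: 7 (faces), 19 (faces+edges) or 27 (full
#'   3x3x3 cube), all including the center voxel.
#' @param band Optional [frequency_band] tag for the output map.
#' @param variant Optional [parameter_variant] tag.
#' @return A [parameter_map] of W values in \[0, 1\].
#' @export
compute_reho <- function(series, neighborhood = 27L,
                         band = frequency_band(0.01, 0.10, closed_high = TRUE),
                         variant = parameter_variant("reho", FALSE, FALSE)) {
  y <- series_matrix(series)
  nbr <- neighbor_index_matrix(series$brain_mask, neighborhood)
  vals <- reho_matrix(y, nbr)
  map_from_values(series, vals, variant, band)
}

#' Hurst exponent by detrended fluctuation analysis (DFA-1)
#'
#' Per voxel: cumulative sum of the mean-centered series, partition into
#' non-overlapping windows at each scale, order-1 polynomial detrend per
#' window, RMS fluctuation F(s); the exponent is the least-squares slope of
#' log F(s) versus log s. White noise gives ~0.5; persistent signals > 0.5.
#' Constant (degenerate) voxels get the missing code (`NA`) and are counted.
#'
#' @param series A [bold_series] (variant-appropriate preprocessing applied
#'   by the caller).
#' @param scales Window lengths; default >= 8 log-spaced scales in \[4, n/4\].
#' @param band,variant Optional tags for the output map.
#' @return A [parameter_map] of exponents.
#' @export
compute_hurst <- function(series, scales = NULL,
                          band = frequency_band(0.01, 0.10, closed_high = TRUE),
                          variant = parameter_variant("he", TRUE, FALSE)) {
  vals <- hurst_matrix(series_matrix(series), scales)
  map_from_values(series, vals, variant, band)
}

#' Time-shift analysis (TSA) lag map
#'
#' Per voxel: Pearson correlation against the reference series at every
#' integer lag in \[-max_lag, +max_lag\]; the map value is the lag (in TR
#' units) maximizing the signed correlation. Positive lag means the voxel
#' series is delayed relative to the reference. Ties are broken toward the
#' smallest |lag|, then toward the negative lag. Zero-variance voxels (or a
#' zero-variance reference) yield the missing code.
#'
#' @param series A [bold_series].
#' @param reference Numeric reference series of the same length; by default
#'   computed by the caller as the mean series over healthy brain.
#' @param max_lag Maximum |lag| in TR units (default 3).
#' @param band,variant Optional tags for the output map.
#' @return A [parameter_map] of integer lags in TR units.
#' @export
compute_tsa <- function(series, reference, max_lag = 3L,
                        band = frequency_band(0.01, 0.10, closed_high = TRUE),
                        variant = parameter_variant("tsa", TRUE, FALSE)) {
  vals <- tsa_matrix(series_matrix(series), reference, max_lag)
  map_from_values(series, vals, variant, band)
}
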