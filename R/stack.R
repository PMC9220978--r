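#' Subject bundle
#'
#' The per-subject inputs of the pipeline: a co-registered BOLD series, its
#' nuisance regressor table, and the tumor subregion masks.
#'
#' @param series A [bold_series].
#' @param nuisance A [nuisance_table] with one row per acquired volume (or per
#'   retained volume).
#' @param rois An [roi_set] on the series grid.
#' @param subject_id Character id.
#' @return A `subject_bundle` object.
#' @export
subject_bundle <- function(series, nuisance, rois, subject_id = "subj") {
  stopifnot(inherits(series, "bold_series"), inherits(rois, "roi_set"))
  structure(
    list(series = series, nuisance = nuisance, rois = rois,
         subject_id = as.character(subject_id)),
    class = "subject_bundle"
  )
}

#' Stack options
#'
#' Tunables of the per-subject map stack; defaults follow the conventional
#' resting-state pipeline (5 discarded volumes, 6 mm smoothing, 27-voxel ReHo
#' neighborhood, max TSA lag 3 TR, DFA scales chosen from the series length).
#'
#' @param discard Leading volumes to drop.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param neighborhood ReHo neighborhood (7/19/27).
#' @param max_lag TSA maximum |lag| in TR units.
#' @param scales DFA window lengths (`NULL` = automatic).
#' @param voxels `"all"` evaluates every in-mask voxel; `"roi"` restricts the
#'   engines to the tumor subregion voxels (plus the neighbors ReHo needs),
#'   which yields identical ROI summaries at a fraction of the cost.
#' @return A named list of options.
#' @export
stack_options <- function(discard = 5L, fwhm_mm = 6, neighborhood = 27L,
                          max_lag = 3L, scales = NULL,
                          voxels = c("all", "roi")) {
  list(discard = as.integer(discard), fwhm_mm = fwhm_mm,
       neighborhood = as.integer(neighborhood), max_lag = as.integer(max_lag),
       scales = scales, voxels = match.arg(voxels))
}

# align a nuisance table with a series truncated by `discard` volumes
align_nuisance <- function(nuisance, t_full, k) {
  if (is.null(nuisance)) {
    stop("subject bundle has no nuisance table; nuisance regression cannot run")
  }
  nr <- nrow(nuisance)
  if (nr == t_full) return(discard_initial_rows(nuisance, k))
  if (nr == t_full - k) return(nuisance)
  stop("nuisance table has ", nr, " rows; expected ", t_full, " or ", t_full - k)
}

#' Compute the full stack of parameter maps for one subject
#'
#' Runs the fixed pipeline order (discard leading volumes, smooth where the
#' variant calls for it, nuisance regression with or without the global
#' signal, ideal band-pass) and evaluates every requested (variant, band)
#' cell. At the defaults this is 14 variants x 10 bands = 140 maps, ordered
#' variant-major then band-minor. The run log attribute records the pipeline
#' order and parameters.
#'
#' @param bundle A [subject_bundle].
#' @param bands List of [frequency_band]s; default [make_band_set()].
#' @param variants List of [parameter_variant]s; default [admissible_variants()].
#' @param options A [stack_options()] list.
#' @return A list of [parameter_map]s with a `run_log` attribute.
#' @export
compute_variant_stack <- function(bundle,
                                  bands = make_band_set(bundle$series$tr),
                                  variants = admissible_variants(),
                                  options = stack_options()) {
  stopifnot(inherits(bundle, "subject_bundle"))
  series <- bundle$series
  t_full <- n_volumes(series)
  nuis <- align_nuisance(bundle$nuisance, t_full, options$discard)
  for (b in bands) check_band_valid(b, series$tr)

  base <- discard_initial_volumes(series, options$discard)
  n <- n_volumes(base)
  tr <- base$tr
  mask <- base$brain_mask
  healthy_cols <- which(as.vector(mask)[as.vector(mask)] &
                          !as.vector(roi_union(bundle$rois))[as.vector(mask)])
  if (length(healthy_cols) == 0L) stop("no healthy brain voxels outside the tumor ROIs")

  need_smoothed <- any(vapply(variants, function(v) v$smoothed, logical(1)))
  need_unsmoothed <- any(vapply(variants, function(v) !v$smoothed, logical(1)))
  need_gsr <- unique(vapply(variants, function(v) v$global_regressed, logical(1)))

  design0 <- cbind(intercept = rep(1, n), unclass(nuis))
  qr0 <- qr(design0)
  if (qr0$rank < ncol(design0)) {
    bad <- colnames(design0)[qr0$pivot[(qr0$rank + 1L):ncol(design0)]]
    stop("nuisance design is rank-deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  trend_qr <- qr(cbind(1, seq_len(n)))

  stream_key <- function(sm, gsr) paste0(if (sm) "s" else "ns", "_", if (gsr) "gsr" else "nogsr")
  streams <- new.env(parent = emptyenv())
  for (sm in c(TRUE, FALSE)) {
    if ((sm && !need_smoothed) || (!sm && !need_unsmoothed)) next
    src <- series_matrix(if (sm) smooth_gaussian(base, options$fwhm_mm) else base)
    for (gsr in need_gsr) {
      resid <- if (gsr) {
        design <- cbind(design0, global = rowMeans(src[, healthy_cols, drop = FALSE]))
        qrg <- qr(design)
        if (qrg$rank < ncol(design)) {
          stop("nuisance design with global signal is rank-deficient")
        }
        qr.resid(qrg, src)
      } else {
        qr.resid(qr0, src)
      }
      d <- qr.resid(trend_qr, resid)
      assign(stream_key(sm, gsr),
             list(detrended = d, fft = stats::mvfft(d)),
             envir = streams)
    }
  }

  # voxel sets: full brain, or the ROI voxels (plus their ReHo neighbors)
  # when only ROI summaries are needed downstream
  v_brain <- sum(mask)
  roi_only <- identical(options$voxels, "roi")
  nbr_full <- if (any(vapply(variants, function(v) v$base == "reho", logical(1)))) {
    neighbor_index_matrix(mask, options$neighborhood)
  } else NULL
  if (roi_only) {
    engine_cols <- which(as.vector(roi_union(bundle$rois))[as.vector(mask)])
    rank_cols <- if (is.null(nbr_full)) engine_cols else {
      nb <- nbr_full[engine_cols, , drop = FALSE]
      sort(unique(nb[nb >= 0L] + 1L))
    }
  } else {
    engine_cols <- seq_len(v_brain)
    rank_cols <- engine_cols
  }
  nbr <- if (!is.null(nbr_full)) {
    # remap neighbor indices into the rank-column subset, rows = engine voxels
    nb <- nbr_full[engine_cols, , drop = FALSE]
    remap <- rep(-1L, v_brain)
    remap[rank_cols] <- seq_along(rank_cols) - 1L
    nb[nb >= 0L] <- remap[nb[nb >= 0L] + 1L]
    nb
  } else NULL
  engine_in_rank <- match(engine_cols, rank_cols)

  filt_cache <- new.env(parent = emptyenv())
  filtered <- function(sm, gsr, bi) {
    # band-filtered series for the rank-column subset
    key <- paste0(stream_key(sm, gsr), "_b", bi)
    if (!exists(key, envir = filt_cache)) {
      st <- get(stream_key(sm, gsr), envir = streams)
      bins <- band_bin_indices(n, tr, bands[[bi]])
      if (length(bins) && max(bins) < n / 2) {
        # synthesize the band directly from its DFT coefficients (exactly the
        # ideal filter, one BLAS multiply instead of an inverse FFT)
        b <- band_synthesis_basis(n, tr, bands[[bi]])
        sub <- st$fft[bins + 1L, rank_cols, drop = FALSE]
        assign(key, b %*% rbind(Re(sub), Im(sub)), envir = filt_cache)
      } else {
        keep <- band_fft_mask(n, tr, bands[[bi]])
        sp <- st$fft[, rank_cols, drop = FALSE]
        sp[!keep, ] <- 0
        assign(key, inv_real_mvfft(sp), envir = filt_cache)
      }
    }
    get(key, envir = filt_cache)
  }

  engine_cache <- new.env(parent = emptyenv())
  filtered_engine <- function(sm, gsr, bi) {
    key <- paste0(stream_key(sm, gsr), "_b", bi)
    if (!exists(key, envir = engine_cache)) {
      assign(key, filtered(sm, gsr, bi)[, engine_in_rank, drop = FALSE],
             envir = engine_cache)
    }
    get(key, envir = engine_cache)
  }

  refsp_cache <- new.env(parent = emptyenv())
  healthy_spectrum <- function(sm, gsr) {
    key <- stream_key(sm, gsr)
    if (!exists(key, envir = refsp_cache)) {
      st <- get(key, envir = streams)
      assign(key, rowMeans(st$fft[, healthy_cols, drop = FALSE]),
             envir = refsp_cache)
    }
    get(key, envir = refsp_cache)
  }

  reference_series <- function(sm, gsr, bi) {
    # band-filtered mean series over healthy brain (linearity of the filter)
    ref_sp <- healthy_spectrum(sm, gsr)
    bins <- band_bin_indices(n, tr, bands[[bi]])
    if (length(bins) && max(bins) < n / 2) {
      b <- band_synthesis_basis(n, tr, bands[[bi]])
      as.vector(b %*% c(Re(ref_sp[bins + 1L]), Im(ref_sp[bins + 1L])))
    } else {
      keep <- band_fft_mask(n, tr, bands[[bi]])
      ref_sp[!keep] <- 0
      inv_real_mvfft(matrix(ref_sp, ncol = 1))[, 1]
    }
  }

  amp_cache <- new.env(parent = emptyenv())
  amplitude <- function(sm, gsr) {
    key <- stream_key(sm, gsr)
    if (!exists(key, envir = amp_cache)) {
      st <- get(key, envir = streams)
      k <- seq_len(floor(n / 2))
      assign(key, 2 * Mod(st$fft[k + 1L, engine_cols, drop = FALSE]) / n,
             envir = amp_cache)
    }
    get(key, envir = amp_cache)
  }

  maps <- vector("list", length(variants) * length(bands))
  i <- 0L
  for (v in variants) {
    for (bi in seq_along(bands)) {
      band <- bands[[bi]]
      vals <- switch(v$base,
        alff = {
          bins <- band_bin_indices(n, tr, band)
          if (length(bins) < 2L) stop("band '", band$name, "' has < 2 DFT bins")
          colMeans(amplitude(v$smoothed, v$global_regressed)[bins, , drop = FALSE])
        },
        falff = {
          bins <- band_bin_indices(n, tr, band)
          if (length(bins) < 2L) stop("band '", band$name, "' has < 2 DFT bins")
          a <- amplitude(v$smoothed, v$global_regressed)
          num <- colSums(a[bins, , drop = FALSE])
          den <- colSums(a)
          ifelse(den > 0, num / den, 0)
        },
        reho = {
          ranks <- cpp_midranks(filtered(v$smoothed, v$global_regressed, bi))
          if (nrow(ranks) < 3L) stop("ReHo needs at least 3 time points")
          cpp_kendall_w(ranks, nbr)
        },
        he = hurst_matrix(filtered_engine(v$smoothed, v$global_regressed, bi),
                          options$scales),
        tsa = {
          f <- filtered_engine(v$smoothed, v$global_regressed, bi)
          ref <- reference_series(v$smoothed, v$global_regressed, bi)
          tsa_matrix(f, ref, options$max_lag)
        }
      )
      i <- i + 1L
      full <- rep(NA_real_, v_brain)
      full[engine_cols] <- vals
      m <- map_from_values(base, full, v, band)
      m$n_missing <- sum(is.na(vals))
      maps[[i]] <- m
    }
  }
  attr(maps, "run_log") <- list(
    subject_id = bundle$subject_id,
    pipeline = c("discard_initial_volumes", "smooth_gaussian(variant streams)",
                 "regress_nuisance", "bandpass"),
    options = options[c("discard", "fwhm_mm", "neighborhood", "max_lag", "voxels")],
    n_volumes_used = n,
    n_maps = i,
    n_missing_total = sum(vapply(maps, function(m) m$n_missing, integer(1)))
  )
  maps
}
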