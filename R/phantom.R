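#' Phantom configuration
#'
#' Describes a synthetic co-registered BOLD acquisition with known ground
#' truth: grid geometry, acquisition constants (405 volumes at TR = 1 s by
#' default), per-region band-limited oscillation components, hemodynamic lags
#' in TR units, Hurst-shaped noise targets, and white-noise level. Regions are
#' `background` (healthy brain) plus the three tumor subregions.
#'
#' All oscillation components are band-filtered versions of one shared
#' broadband driver signal, so regions with overlapping bands are coherent and
#' lags are recoverable by cross-correlation.
#'
#' @param grid_shape Voxels per axis (3 ints, each >= 8).
#' @param n_volumes Number of volumes (>= 16).
#' @param tr Repetition time in seconds.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @param tissue_specs Named list (`background`, `enhancement`,
#'   `non_enhancement`, `edema`) of lists of components, each a
#'   `list(band = frequency_band(...), amplitude = <sd, a.u.>)`.
#' @param noise_sd White-noise standard deviation (a.u.).
#' @param hurst_sd Standard deviation of the Hurst-shaped noise process;
#'   scalar or named per region.
#' @param lag_field Named per-region lag in TR units (integers; applied as a
#'   circular shift of the oscillation components).
#' @param hurst_target Named per-region target Hurst exponent in (0, 1).
#' @param baseline Mean intensity offset (a.u.).
#' @param nuisance_weight Weight with which the white-matter and CSF nuisance
#'   series leak into voxel signals.
#' @param region_shape `"block"` (axis-aligned cubes, default) or `"sphere"`.
#' @param seed Integer seed; identical configs give bit-identical phantoms.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(grid_shape = c(10L, 10L, 10L),
                           n_volumes = 405L,
                           tr = 1.0,
                           voxel_size_mm = c(3.4375, 3.4375, 6.5),
                           tissue_specs = default_tissue_specs(),
                           noise_sd = 0.5,
                           hurst_sd = 0.5,
                           lag_field = c(background = 0, enhancement = 0,
                                         non_enhancement = 0, edema = 0),
                           hurst_target = c(background = 0.5, enhancement = 0.5,
                                            non_enhancement = 0.5, edema = 0.5),
                           baseline = 100,
                           nuisance_weight = 0.2,
                           region_shape = c("block", "sphere"),
                           seed = 1L) {
  region_shape <- match.arg(region_shape)
  grid_shape <- as.integer(grid_shape)
  n_volumes <- as.integer(n_volumes)
  stopifnot(length(grid_shape) == 3L)
  if (any(grid_shape < 8L)) stop("grid_shape must be >= 8 on every axis")
  if (n_volumes < 16L) stop("n_volumes must be >= 16")
  if (!(tr > 0)) stop("tr must be positive")
  regions <- c("background", roi_names())
  if (!all(regions %in% names(tissue_specs))) {
    stop("tissue_specs must name every region: ", paste(regions, collapse = ", "))
  }
  for (rg in regions) {
    for (comp in tissue_specs[[rg]]) {
      check_band_valid(comp$band, tr)
    }
  }
  if (length(hurst_sd) == 1L && is.null(names(hurst_sd))) {
    hurst_sd <- stats::setNames(rep(hurst_sd, 4L), regions)
  }
  for (nm in regions) {
    h <- hurst_target[[nm]]
    if (!(h > 0 && h < 1)) stop("hurst_target['", nm, "'] must lie in (0, 1)")
  }
  structure(
    list(grid_shape = grid_shape, n_volumes = n_volumes, tr = tr,
         voxel_size_mm = voxel_size_mm, tissue_specs = tissue_specs,
         noise_sd = noise_sd, hurst_sd = hurst_sd,
         lag_field = lag_field, hurst_target = hurst_target,
         baseline = baseline, nuisance_weight = nuisance_weight,
         region_shape = region_shape, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Default per-region oscillation components
#'
#' One low-frequency component per region, with overlapping bands so the
#' healthy-brain reference and the tumor subregions are mutually coherent,
#' plus a high-frequency (0.15-0.25 Hz) component standing in for
#' cardiorespiratory content above the analysis range; the latter gives the
#' fractional-amplitude measures a non-trivial denominator.
#'
#' @return Named list of component lists, one per region.
#' @export
default_tissue_specs <- function() {
  hf <- function() list(band = frequency_band(0.15, 0.25), amplitude = 0.6)
  list(
    background      = list(list(band = frequency_band(0.01, 0.08), amplitude = 1.0), hf()),
    enhancement     = list(list(band = frequency_band(0.03, 0.06), amplitude = 1.2), hf()),
    non_enhancement = list(list(band = frequency_band(0.02, 0.05), amplitude = 1.0), hf()),
    edema           = list(list(band = frequency_band(0.03, 0.07), amplitude = 1.0), hf())
  )
}

# region masks: brain = interior block (1-voxel margin), three disjoint
# subregion blocks (or spheres) inside it
phantom_region_masks <- function(config) {
  d <- config$grid_shape
  brain <- array(FALSE, dim = d)
  brain[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  lo <- c(3L, 3L, 3L)
  hi <- d - 2L
  centers <- list(
    enhancement     = c(lo[1], lo[2], lo[3]),
    non_enhancement = c(hi[1], hi[2], lo[3]),
    edema           = c(lo[1], hi[2], hi[3])
  )
  half <- 1L  # 3x3x3 blocks / radius-1.5 spheres
  mk <- function(ctr) {
    m <- array(FALSE, dim = d)
    if (config$region_shape == "block") {
      m[(ctr[1] - half):(ctr[1] + half),
        (ctr[2] - half):(ctr[2] + half),
        (ctr[3] - half):(ctr[3] + half)] <- TRUE
    } else {
      idx <- which(brain, arr.ind = TRUE)
      r2 <- rowSums(sweep(idx, 2, ctr)^2)
      m[idx[r2 <= 2.5, , drop = FALSE]] <- TRUE
    }
    m & brain
  }
  masks <- lapply(centers, mk)
  rois <- roi_set(masks$enhancement, masks$non_enhancement, masks$edema,
                  brain_mask = brain)
  list(brain = brain, rois = rois)
}

# shared broadband driver with unit-amplitude spectrum and seeded phases
phantom_driver_spectrum <- function(n) {
  kmax <- floor((n - 1) / 2)
  phases <- stats::runif(kmax, 0, 2 * pi)
  sp <- complex(length.out = n)
  sp[1 + seq_len(kmax)] <- exp(1i * phases)
  sp[n + 1 - seq_len(kmax)] <- Conj(sp[1 + seq_len(kmax)])
  sp
}

# band-limited canonical signal from the shared driver, scaled to sd = amplitude
phantom_component_signal <- function(driver_sp, n, tr, band, amplitude) {
  keep <- band_fft_mask(n, tr, band)
  sp <- driver_sp
  sp[!keep] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) stop("band '", band$name, "' has no DFT support at n = ", n, ", tr = ", tr)
  amplitude * x / s
}

circular_shift <- function(x, lag) {
  n <- length(x)
  lag <- ((round(lag)) %% n + n) %% n
  if (lag == 0) return(x)
  c(x[(n - lag + 1):n], x[1:(n - lag)])
}

# spectrally synthesized noise with power ~ f^(1 - 2H), one column per voxel,
# each scaled to sd = sd_target
phantom_hurst_noise <- function(n, tr, h, n_voxels, sd_target) {
  if (sd_target <= 0 || n_voxels == 0L) return(matrix(0, n, n_voxels))
  kmax <- floor((n - 1) / 2)
  f <- (seq_len(kmax)) / (n * tr)
  amp <- f^((1 - 2 * h) / 2)
  phases <- matrix(stats::runif(kmax * n_voxels, 0, 2 * pi), kmax, n_voxels)
  sp <- matrix(complex(length.out = n * n_voxels), n, n_voxels)
  sp[1 + seq_len(kmax), ] <- amp * exp(1i * phases)
  sp[n + 1 - seq_len(kmax), ] <- Conj(sp[1 + seq_len(kmax), , drop = FALSE])
  x <- Re(stats::mvfft(sp, inverse = TRUE)) / n
  sds <- apply(x, 2, stats::sd)
  sweep(x, 2, ifelse(sds > 0, sds, 1), "/") * sd_target
}

# smooth low-frequency nuisance series (for wm/csf and motion drifts)
phantom_slow_series <- function(n, tr, high_hz = 0.05) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  k <- seq_len(floor(n / 2))
  keep <- rep(FALSE, n)
  keep_pos <- k[k / (n * tr) <= high_hz]
  keep[keep_pos + 1L] <- TRUE
  keep[n + 1L - keep_pos] <- TRUE
  sp[!keep] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  as.vector(scale(y))
}

#' Generate a synthetic BOLD phantom
#'
#' Builds a co-registered 4D BOLD series, the three tumor subregion masks, a
#' nuisance regressor table (six motion parameters plus white-matter and CSF
#' means, the latter two leaked into the voxel signals), and a ground-truth
#' record. Each in-brain voxel is the sum of its region's band-limited
#' oscillation components (circularly shifted by the region's lag), a noise
#' process spectrally shaped to the region's target Hurst exponent, and white
#' noise. Identical configs give bit-identical output.
#'
#' @param config A [phantom_config].
#' @return A list with elements `series` ([bold_series]), `rois` ([roi_set]),
#'   `nuisance` ([nuisance_table], one row per acquired volume), and
#'   `ground_truth` (list).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_volumes
  tr <- config$tr
  geo <- phantom_region_masks(config)
  brain <- geo$brain
  rois <- geo$rois
  v_total <- sum(brain)

  region_of <- array("", dim = config$grid_shape)
  region_of[brain] <- "background"
  for (nm in roi_names()) region_of[rois[[nm]]] <- nm
  region_cols <- lapply(c("background", roi_names()), function(nm) {
    which(region_of[brain] == nm)
  })
  names(region_cols) <- c("background", roi_names())

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  driver <- phantom_driver_spectrum(n)
  y <- matrix(0, n, v_total)
  for (nm in names(region_cols)) {
    cols <- region_cols[[nm]]
    if (length(cols) == 0L) next
    sig <- numeric(n)
    for (comp in config$tissue_specs[[nm]]) {
      s <- phantom_component_signal(driver, n, tr, comp$band, comp$amplitude)
      sig <- sig + circular_shift(s, config$lag_field[[nm]])
    }
    y[, cols] <- sig
    y[, cols] <- y[, cols] + phantom_hurst_noise(
      n, tr, config$hurst_target[[nm]], length(cols), config$hurst_sd[[nm]]
    )
  }
  if (config$noise_sd > 0) {
    y <- y + matrix(stats::rnorm(n * v_total, sd = config$noise_sd), n, v_total)
  }

  wm <- phantom_slow_series(n, tr)
  csf <- phantom_slow_series(n, tr)
  if (config$nuisance_weight != 0) {
    y <- y + config$nuisance_weight * (wm + csf)
  }
  y <- y + config$baseline

  motion <- vapply(seq_len(6L), function(i) cumsum(stats::rnorm(n, sd = 0.02)),
                   numeric(n))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  nuis <- nuisance_table(cbind(motion, wm_mean = wm, csf_mean = csf))

  arr <- array(0, dim = c(config$grid_shape, n))
  flat <- matrix(arr, prod(config$grid_shape), n)
  flat[as.vector(brain), ] <- t(y)
  arr <- array(flat, dim = c(config$grid_shape, n))

  series <- bold_series(arr, tr = tr, brain_mask = brain,
                        voxel_size_mm = config$voxel_size_mm)
  gt <- list(
    planted_lags = as.list(config$lag_field),
    hurst_target = as.list(config$hurst_target),
    seed = config$seed
  )
  list(series = series, rois = rois, nuisance = nuis, ground_truth = gt)
}

# save/restore the global RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labeled phantom cohort with planted effects
#'
#' Draws `n_subjects` phantoms with per-subject seeds derived from the config
#' seed. Positive-class subjects have their generating parameters perturbed so
#' the named features shift: TSA effects shift the region lag by `delta` TR
#' and HE effects shift the region's target Hurst exponent by `delta` (both
#' exactly, in feature units). ALFF and ReHo effects raise the region's
#' oscillation amplitude in the named band (ALFF by `delta * sqrt(m/2)` a.u.,
#' m = in-band DFT bins, moving the band-mean amplitude by about `delta`
#' before smoothing; ReHo on the raw generator amplitude scale). fALFF
#' effects reduce the region's high-frequency component amplitudes by
#' `delta` (floored at zero; negative `delta` raises them), concentrating
#' spectral content into the low-frequency range without touching the in-band
#' signal the other parameters see.
#'
#' @param config A [phantom_config]; its seed drives labels and all subjects.
#' @param n_subjects Number of subjects (>= 4).
#' @param effects List of `list(feature = <feature name>, delta = <shift>)`.
#' @param label_balance Fraction of positive labels in (0, 1).
#' @param amplitude_jitter_sd Log-normal sd of per-subject amplitude jitter.
#' @return A list with `subjects` (list of [subject_bundle]), `labels`
#'   (integer 0/1 vector named by subject id), and `ground_truth`.
#' @export
generate_cohort <- function(config, n_subjects, effects = list(),
                            label_balance = 0.5, amplitude_jitter_sd = 0.1) {
  stopifnot(inherits(config, "phantom_config"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 4L) stop("n_subjects must be >= 4")
  if (!(label_balance > 0 && label_balance < 1)) stop("label_balance must be in (0, 1)")
  bands <- make_band_set(config$tr)
  band_names <- vapply(bands, function(b) b$name, character(1))
  parsed <- lapply(effects, function(e) {
    p <- parse_feature_name(e$feature)
    if (!(p$band %in% band_names)) {
      stop("unknown band '", p$band, "' in feature '", e$feature, "'")
    }
    p$delta <- e$delta
    p$band_obj <- bands[[match(p$band, band_names)]]
    p
  })

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n_pos <- round(label_balance * n_subjects)
  labels <- integer(n_subjects)
  labels[sample.int(n_subjects, n_pos)] <- 1L
  subject_seeds <- config$seed + 1000L + seq_len(n_subjects)

  # n volumes used after the conventional 5-volume discard
  n_post <- config$n_volumes - 5L

  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg_i <- config
    cfg_i$seed <- subject_seeds[i]
    set.seed(subject_seeds[i])
    jit <- exp(stats::rnorm(1, sd = amplitude_jitter_sd))
    for (rg in names(cfg_i$tissue_specs)) {
      for (j in seq_along(cfg_i$tissue_specs[[rg]])) {
        cfg_i$tissue_specs[[rg]][[j]]$amplitude <-
          cfg_i$tissue_specs[[rg]][[j]]$amplitude * jit
      }
    }
    if (labels[i] == 1L) {
      for (p in parsed) {
        if (p$base == "tsa") {
          cfg_i$lag_field[[p$roi]] <- cfg_i$lag_field[[p$roi]] + round(p$delta)
        } else if (p$base == "he") {
          h <- cfg_i$hurst_target[[p$roi]] + p$delta
          cfg_i$hurst_target[[p$roi]] <- min(max(h, 0.05), 0.95)
        } else if (p$base == "falff") {
          specs <- cfg_i$tissue_specs[[p$roi]]
          for (j in seq_along(specs)) {
            if (specs[[j]]$band$low >= 0.1) {
              specs[[j]]$amplitude <- max(0, specs[[j]]$amplitude - p$delta)
            }
          }
          cfg_i$tissue_specs[[p$roi]] <- specs
        } else {
          amp <- if (p$base == "alff") {
            m <- length(band_bin_indices(n_post, config$tr, p$band_obj))
            p$delta * sqrt(m / 2)
          } else {
            p$delta
          }
          cfg_i$tissue_specs[[p$roi]] <- c(
            cfg_i$tissue_specs[[p$roi]],
            list(list(band = p$band_obj, amplitude = amp))
          )
        }
      }
    }
    ph <- generate_phantom(cfg_i)
    subjects[[i]] <- subject_bundle(ph$series, ph$nuisance, ph$rois,
                                    subject_id = sprintf("sub%03d", i))
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  names(labels) <- ids
  gt <- list(
    planted_effects = lapply(effects, function(e) e[c("feature", "delta")]),
    planted_lags = as.list(config$lag_field),
    seed = config$seed,
    subject_seeds = subject_seeds
  )
  list(subjects = subjects, labels = labels, ground_truth = gt)
}

#' Write a phantom to disk
#'
#' Writes the series and the integer-label mask as NIfTI, the nuisance table
#' as whitespace-delimited text, and the ground truth as JSON.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    series = file.path(dir, paste0(prefix, "_bold.nii.gz")),
    rois = file.path(dir, paste0(prefix, "_rois.nii.gz")),
    nuisance = file.path(dir, paste0(prefix, "_nuisance.txt")),
    ground_truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_bold(phantom$series, paths["series"])
  write_roi_labels(phantom$rois, paths["rois"],
                   voxel_size_mm = voxel_sizes_mm(phantom$series))
  write_nuisance(phantom$nuisance, paths["nuisance"])
  jsonlite::write_json(phantom$ground_truth, paths["ground_truth"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
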