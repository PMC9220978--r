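#' Feature name grammar
#'
#' Feature names encode the full provenance of each value:
#' `<base>_<s|ns>_<gsr|nogsr>_<band-name>_<roi-name>`, e.g.
#' `tsa_ns_gsr_0.03-0.04_enhancement`. This makes importance listings directly
#' interpretable as (parameter, preprocessing, frequency band, lesion area).
#'
#' @param variant A [parameter_variant].
#' @param band A [frequency_band].
#' @param roi One of `"enhancement"`, `"non_enhancement"`, `"edema"`.
#' @return Character scalar.
#' @export
feature_name <- function(variant, band, roi) {
  roi <- match.arg(roi, roi_names())
  paste(variant_label(variant), band$name, roi, sep = "_")
}

#' Parse a feature name back into its components
#'
#' @param name A feature name produced by [feature_name()].
#' @return A list with `base`, `smoothed`, `global_regressed`, `band` (name),
#'   `roi`.
#' @export
parse_feature_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) < 5L) stop("malformed feature name '", name, "'")
  base <- parts[1]
  if (!base %in% c("alff", "falff", "reho", "he", "tsa")) {
    stop("unknown parameter base '", base, "' in feature '", name, "'")
  }
  if (!parts[2] %in% c("s", "ns")) stop("malformed smooth flag in '", name, "'")
  if (!parts[3] %in% c("gsr", "nogsr")) stop("malformed GSR flag in '", name, "'")
  roi <- paste(parts[5:length(parts)], collapse = "_")
  if (!roi %in% roi_names()) stop("unknown ROI '", roi, "' in feature '", name, "'")
  list(base = base, smoothed = parts[2] == "s",
       global_regressed = parts[3] == "gsr", band = parts[4], roi = roi)
}

#' Expected feature names for a config product
#'
#' Deterministic order: variant-major, then band, then ROI.
#'
#' @param variants List of [parameter_variant]s.
#' @param bands List of [frequency_band]s.
#' @param rois Character vector of ROI names.
#' @return Character vector of length `|variants| * |bands| * |rois|` (420 at
#'   the defaults).
#' @export
feature_names <- function(variants = admissible_variants(),
                          bands = make_band_set(),
                          rois = roi_names()) {
  out <- character(0)
  for (v in variants) {
    for (b in bands) {
      for (r in rois) out <- c(out, feature_name(v, b, r))
    }
  }
  out
}

#' Reduce a stack of parameter maps to one feature row
#'
#' The feature value for a (map, ROI) cell is the mean of the map over the
#' in-mask, non-missing voxels of that ROI. An ROI that is fully missing for a
#' map yields `NA` (imputation happens at modeling time, on training data
#' only) and is recorded in the `n_missing_cells` attribute.
#'
#' @param maps List of [parameter_map]s (e.g. from [compute_variant_stack()]).
#' @param rois An [roi_set] on the same grid as the maps.
#' @return Named numeric vector, one value per (map, ROI), ordered map-major.
#' @export
extract_roi_means <- function(maps, rois) {
  grid <- dim(rois$enhancement)
  vals <- numeric(0)
  nms <- character(0)
  n_missing_cells <- 0L
  for (m in maps) {
    if (!identical(dim(m$values), grid)) {
      stop("parameter map grid ", paste(dim(m$values), collapse = "x"),
           " does not match ROI grid ", paste(grid, collapse = "x"))
    }
    for (r in roi_names()) {
      x <- m$values[rois[[r]]]
      x <- x[!is.na(x)]
      v <- if (length(x) == 0L) {
        n_missing_cells <- n_missing_cells + 1L
        NA_real_
      } else {
        mean(x)
      }
      vals <- c(vals, v)
      nms <- c(nms, feature_name(m$variant, m$band, r))
    }
  }
  names(vals) <- nms
  attr(vals, "n_missing_cells") <- n_missing_cells
  vals
}

#' Assemble per-subject feature rows into a feature table
#'
#' @param rows Named list of feature rows (named numeric vectors sharing one
#'   feature-name set), names = subject ids.
#' @param labels Optional binary endpoint, named by subject id or in row
#'   order.
#' @return A tibble with columns `subject_id`, optionally `label`, then the
#'   features in the order of the first row.
#' @export
assemble_feature_table <- function(rows, labels = NULL) {
  if (is.null(names(rows)) || any(names(rows) == "")) {
    stop("rows must be a named list keyed by subject id")
  }
  ids <- names(rows)
  if (anyDuplicated(ids)) {
    stop("duplicated subject id: ", ids[duplicated(ids)][1])
  }
  ref <- names(rows[[1]])
  for (i in seq_along(rows)) {
    if (!setequal(names(rows[[i]]), ref)) {
      stop("subject '", ids[i], "' has an inconsistent feature set")
    }
  }
  mat <- do.call(rbind, lapply(rows, function(r) unclass(r)[ref]))
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(subject_id = ids), out)
  if (!is.null(labels)) {
    lab <- if (!is.null(names(labels))) {
      if (!all(ids %in% names(labels))) stop("labels are missing some subject ids")
      labels[ids]
    } else {
      if (length(labels) != length(ids)) stop("labels length does not match rows")
      labels
    }
    out <- dplyr::mutate(out, label = as.integer(lab), .after = "subject_id")
  }
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "label"))
}

#' Compute the full feature table for a cohort
#'
#' Runs [compute_variant_stack()] and [extract_roi_means()] for every subject
#' and assembles the result; at the defaults this is the 420-column table (14
#' variants x 10 bands x 3 subregions).
#'
#' @param subjects List of [subject_bundle]s.
#' @param labels Optional binary endpoint named by subject id.
#' @param bands,variants,options Passed to [compute_variant_stack()]; by
#'   default the engines are restricted to the ROI voxels (plus ReHo
#'   neighbors), which gives identical ROI means to a whole-brain run.
#' @return A tibble (see [assemble_feature_table()]).
#' @export
cohort_feature_table <- function(subjects, labels = NULL,
                                 bands = NULL, variants = admissible_variants(),
                                 options = stack_options(voxels = "roi")) {
  rows <- list()
  for (s in subjects) {
    b <- if (is.null(bands)) make_band_set(s$series$tr) else bands
    maps <- compute_variant_stack(s, bands = b, variants = variants,
                                  options = options)
    rows[[s$subject_id]] <- extract_roi_means(maps, s$rois)
  }
  assemble_feature_table(rows, labels)
}

#' Write a feature table to CSV
#' @param table Feature table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV written by [write_feature_table()].
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
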