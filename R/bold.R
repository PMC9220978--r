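#' BOLD series container
#'
#' A 4D blood-oxygen-level-dependent (BOLD) intensity array with its sampling
#' interval, brain mask and voxel-to-mm affine. All temporal operations in the
#' package act on this container.
#'
#' @param data 4D numeric array, dimensions (x, y, z, t).
#' @param tr Repetition time (sampling interval) in seconds.
#' @param brain_mask 3D logical array matching the spatial grid. Defaults to
#'   all-`TRUE`.
#' @param affine 4x4 voxel-to-mm matrix. Defaults to a diagonal affine built
#'   from `voxel_size_mm`.
#' @param voxel_size_mm Voxel edge lengths in mm (length 3), used when `affine`
#'   is not given.
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, tr, brain_mask = NULL, affine = NULL,
                        voxel_size_mm = c(3, 3, 3)) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (!(is.numeric(tr) && length(tr) == 1L && tr > 0)) stop("tr must be a positive scalar")
  if (dim(data)[4] < 2L) stop("a BOLD series needs at least 2 volumes")
  sp <- dim(data)[1:3]
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = sp)
  stopifnot(is.logical(brain_mask))
  if (!identical(dim(brain_mask), sp)) stop("brain_mask shape must equal the spatial grid")
  if (is.null(affine)) {
    stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
    affine <- diag(c(voxel_size_mm, 1))
  }
  stopifnot(identical(dim(affine), c(4L, 4L)))
  structure(
    list(data = data, tr = tr, brain_mask = brain_mask, affine = affine),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bold_series> %d x %d x %d voxels, %d volumes, TR = %g s, %d in-mask voxels\n",
    d[1], d[2], d[3], d[4], x$tr, sum(x$brain_mask)
  ))
  invisible(x)
}

#' Number of volumes (time points) in a BOLD series
#' @param series A [bold_series].
#' @return Integer count.
#' @export
n_volumes <- function(series) dim(series$data)[4]

voxel_sizes_mm <- function(series) {
  # column norms of the 3x3 rotation/scale block
  sqrt(colSums(series$affine[1:3, 1:3]^2))
}

#' Extract in-mask voxel time series as a matrix
#'
#' @param series A [bold_series].
#' @param mask Optional 3D logical mask; defaults to the series brain mask.
#' @return A (time x voxel) numeric matrix, columns in array (column-major)
#'   voxel order of the mask.
#' @export
series_matrix <- function(series, mask = series$brain_mask) {
  d <- dim(series$data)
  v <- matrix(series$data, prod(d[1:3]), d[4])
  t(v[as.vector(mask), , drop = FALSE])
}

#' Replace in-mask voxel time series from a matrix
#'
#' Inverse of [series_matrix()]: writes the columns of `mat` back into the
#' voxels selected by `mask` and zeroes nothing else.
#'
#' @inheritParams series_matrix
#' @param mat (time x voxel) matrix with one column per in-mask voxel.
#' @return A new [bold_series].
#' @export
series_from_matrix <- function(series, mat, mask = series$brain_mask) {
  d <- dim(series$data)
  stopifnot(nrow(mat) == d[4], ncol(mat) == sum(mask))
  v <- matrix(series$data, prod(d[1:3]), d[4])
  v[as.vector(mask), ] <- t(mat)
  out <- series
  out$data <- array(v, dim = d)
  out
}

#' Tumor subregion set
#'
#' Three pairwise-disjoint 3D masks named `enhancement`, `non_enhancement` and
#' `edema`, each non-empty and contained in the brain mask when one is given.
#'
#' @param enhancement,non_enhancement,edema 3D logical arrays on a common grid.
#' @param brain_mask Optional 3D logical array; when given, every subregion must
#'   lie inside it.
#' @return A `roi_set` object (named list of the three masks).
#' @export
roi_set <- function(enhancement, non_enhancement, edema, brain_mask = NULL) {
  masks <- list(
    enhancement = enhancement,
    non_enhancement = non_enhancement,
    edema = edema
  )
  dims <- lapply(masks, dim)
  if (!all(vapply(masks, is.logical, logical(1)))) stop("ROI masks must be logical arrays")
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("ROI masks must share one grid")
  }
  for (nm in names(masks)) {
    if (!any(masks[[nm]])) stop("ROI '", nm, "' is empty")
  }
  overlap <- (masks$enhancement & masks$non_enhancement) |
    (masks$enhancement & masks$edema) |
    (masks$non_enhancement & masks$edema)
  if (any(overlap)) stop("ROI masks overlap; subregions must be pairwise disjoint")
  if (!is.null(brain_mask)) {
    for (nm in names(masks)) {
      if (any(masks[[nm]] & !brain_mask)) {
        stop("ROI '", nm, "' extends outside the brain mask")
      }
    }
  }
  structure(masks, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>",
      paste(sprintf("%s: %d vox", names(x), vapply(x, sum, integer(1))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Canonical tumor subregion names
#' @return Character vector: enhancement, non_enhancement, edema.
#' @export
roi_names <- function() c("enhancement", "non_enhancement", "edema")

#' Union of the tumor subregions
#' @param rois A [roi_set].
#' @return 3D logical array.
#' @export
roi_union <- function(rois) rois$enhancement | rois$non_enhancement | rois$edema

#' Read a 4D NIfTI file as a BOLD series
#'
#' @param path NIfTI file (series). The repetition time is taken from the
#'   header `pixdim[4]` unless overridden.
#' @param mask_path Optional NIfTI brain mask (non-zero = in mask).
#' @param tr Optional TR override in seconds.
#' @return A [bold_series].
#' @export
read_bold <- function(path, mask_path = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("'", path, "' is not a 4D series")
  if (is.null(tr)) {
    pd <- attr(img, "pixdim")
    tr <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else
      stop("no TR in the header of '", path, "'; pass tr=")
  }
  mask <- if (!is.null(mask_path)) {
    as.array(RNifti::readNifti(mask_path)) != 0
  } else NULL
  bold_series(arr, tr = tr, brain_mask = mask, affine = RNifti::xform(img))
}

#' Write a BOLD series to NIfTI
#' @param series A [bold_series].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(series, path) {
  vox <- voxel_sizes_mm(series)
  img <- RNifti::asNifti(series$data, pixdim = c(vox, series$tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer-label subregion mask as an `roi_set`
#'
#' Labels: 1 = enhancement, 2 = non-enhancement, 3 = peritumoral edema.
#'
#' @param path NIfTI label image.
#' @param brain_mask Optional 3D logical array to validate containment.
#' @return An [roi_set].
#' @export
read_roi_labels <- function(path, brain_mask = NULL) {
  lab <- round(as.array(RNifti::readNifti(path)))
  roi_set(lab == 1, lab == 2, lab == 3, brain_mask = brain_mask)
}

#' Write an `roi_set` as an integer-label NIfTI
#' @param rois An [roi_set].
#' @param path Output path.
#' @param voxel_size_mm Voxel sizes for the header.
#' @return `path`, invisibly.
#' @export
write_roi_labels <- function(rois, path, voxel_size_mm = c(3, 3, 3)) {
  lab <- array(0L, dim = dim(rois$enhancement))
  lab[rois$enhancement] <- 1L
  lab[rois$non_enhancement] <- 2L
  lab[rois$edema] <- 3L
  img <- RNifti::asNifti(lab, pixdim = c(voxel_size_mm, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}
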