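# Masked-volume ingestion and export.  A set of 3-D NIfTI volumes plus a
# binary mask becomes an n_subjects x n_voxels matrix; canonical vectors map
# back to volumes for visualization.  Column order is the linear index order
# of the mask array (R's column-major order), which is fixed and documented
# because the canonical-vector/image correspondence depends on it.

#' Read a set of masked NIfTI volumes into a subjects-by-voxels matrix
#'
#' The mask is binarized at `> 0`; each subject volume contributes one row
#' holding its in-mask voxel values, columns ordered by the linear index of
#' the mask array.
#'
#' @param image_paths character vector of NIfTI file paths, one per subject,
#'   all on the same grid as the mask.
#' @param mask_path path to the NIfTI mask volume.
#' @param subject_ids optional subject labels; default the file base names.
#' @param global_mean if `TRUE`, subtract each volume's mean over *all*
#'   voxels (in- and out-of-mask) at ingestion. The default leaves scaling
#'   to [mean_scale()], which uses the in-mask mean -- background voxels
#'   would otherwise dilute the session effect being removed. If you scale
#'   here, pass `rescale = FALSE` to [condition_contrast()].
#' @return object of class `masked_image_set`: list with `data` (n x V
#'   matrix), `mask` (logical array), `voxel_index` (linear indices of
#'   in-mask voxels), `reference` (the mask image, carrying grid and affine
#'   for export), and `subject_ids`.
#' @export
read_masked_set <- function(image_paths, mask_path, subject_ids = NULL,
                            global_mean = FALSE) {
  mask_img <- RNifti::readNifti(mask_path)
  mask <- array(as.vector(mask_img) > 0, dim = dim(mask_img))
  voxel_index <- which(mask)
  if (length(voxel_index) == 0) stop("empty mask: no voxels > 0")
  if (is.null(subject_ids)) {
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(image_paths))
  }
  if (length(subject_ids) != length(image_paths)) {
    stop("subject_ids must have one entry per image")
  }

  data <- matrix(NA_real_, nrow = length(image_paths),
                 ncol = length(voxel_index))
  for (i in seq_along(image_paths)) {
    img <- RNifti::readNifti(image_paths[i])
    if (!identical(dim(img)[1:3], dim(mask)[1:3]) || length(dim(img)) != 3) {
      stop(sprintf("grid mismatch: %s does not match the mask grid",
                   image_paths[i]))
    }
    vals <- as.vector(img)[voxel_index]
    if (any(!is.finite(vals))) {
      stop(sprintf("non-finite voxel values inside the mask in %s",
                   image_paths[i]))
    }
    if (global_mean) vals <- vals - mean(as.vector(img))
    data[i, ] <- vals
  }

  structure(
    list(
      data = data, mask = mask, voxel_index = voxel_index,
      reference = mask_img, subject_ids = subject_ids
    ),
    class = "masked_image_set"
  )
}

#' @export
print.masked_image_set <- function(x, ...) {
  cat(sprintf(
    "<masked_image_set> %d subject(s) x %d in-mask voxels (grid %s)\n",
    nrow(x$data), ncol(x$data), paste(dim(x$mask), collapse = " x ")
  ))
  invisible(x)
}

#' Mean-scale scans (remove the per-scan session effect)
#'
#' Subtracts from every scan (row) its own mean over the in-mask voxels, so
#' global session-level offsets do not masquerade as shared structure.
#' Methods exist for numeric vectors (a single scan), matrices (rows =
#' scans), and [`masked_image_set`][read_masked_set] objects.
#'
#' @param x vector, matrix, or `masked_image_set`.
#' @param ... unused.
#' @return object of the same shape with each scan's mean subtracted.
#' @examples
#' mean_scale(c(1, 2, 3))  # -1 0 1
#' @export
mean_scale <- function(x, ...) UseMethod("mean_scale")

#' @export
mean_scale.numeric <- function(x, ...) x - mean(x)

#' @export
mean_scale.matrix <- function(x, ...) x - rowMeans(x)

#' @export
mean_scale.masked_image_set <- function(x, ...) {
  x$data <- mean_scale(x$data)
  x
}

#' Per-subject contrast between two scanning conditions
#'
#' Mean-scales each scan and subtracts the reference condition (e.g.,
#' placebo) from the active condition voxelwise, subject by subject, matched
#' on subject id. The result is the per-subject condition effect, ready to
#' be standardized and fed to [scca()].
#'
#' @param active [`masked_image_set`][read_masked_set] for the active
#'   condition.
#' @param reference `masked_image_set` for the reference condition; must
#'   cover the same subjects (any order) on the same mask.
#' @param rescale mean-scale each scan (in-mask mean) before differencing;
#'   set `FALSE` if scans were already scaled at ingestion.
#' @return `masked_image_set` of differences, subjects ordered as in
#'   `active`.
#' @export
condition_contrast <- function(active, reference, rescale = TRUE) {
  stopifnot(inherits(active, "masked_image_set"),
            inherits(reference, "masked_image_set"))
  if (!identical(active$voxel_index, reference$voxel_index) ||
      !identical(dim(active$mask), dim(reference$mask))) {
    stop("condition sets must share the same mask")
  }
  idx <- match(active$subject_ids, reference$subject_ids)
  if (any(is.na(idx))) {
    stop(sprintf(
      "subjects missing from the reference condition: %s",
      paste(active$subject_ids[is.na(idx)], collapse = ", ")
    ))
  }
  out <- active
  ref <- reference$data[idx, , drop = FALSE]
  out$data <- if (rescale) {
    mean_scale(active$data) - mean_scale(ref)
  } else {
    active$data - ref
  }
  out
}

#' Write a weight vector as a NIfTI volume
#'
#' Renders a canonical vector in the original voxel space: in-mask voxels
#' take the weight values (zero-variance-dropped columns must already be
#' re-inflated with [inflate_weights()]), out-of-mask voxels are 0, and the
#' grid/affine are copied from the mask.
#'
#' @param w numeric vector, one value per in-mask voxel of `set`.
#' @param set a [`masked_image_set`][read_masked_set] providing mask and
#'   header.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_weight_map <- function(w, set, path) {
  stopifnot(inherits(set, "masked_image_set"))
  if (length(w) != length(set$voxel_index)) {
    stop("length(w) must equal the number of in-mask voxels")
  }
  vol <- array(0, dim = dim(set$mask))
  vol[set$voxel_index] <- w
  img <- RNifti::asNifti(vol, reference = set$reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a data matrix as a set of masked NIfTI volumes
#'
#' Inverse of [read_masked_set()] for fixture and simulation export: packs
#' each row of `X` into the first `ncol(X)` voxels (linear index order) of a
#' 3-D grid, writes one volume per row plus the binary mask.
#'
#' @param X numeric matrix (subjects x voxels), `ncol(X) <= prod(grid_dim)`.
#' @param dir output directory (created if needed).
#' @param grid_dim integer length-3 grid dimensions.
#' @param subject_ids labels used in the volume file names.
#' @param compress write `.nii.gz` (default `FALSE`: plain `.nii`).
#' @return list with `mask` path and `images` paths, invisibly.
#' @export
write_volume_set <- function(X, dir, grid_dim = c(10, 10, 10),
                             subject_ids = NULL, compress = FALSE) {
  X <- as.matrix(X)
  if (length(grid_dim) != 3) stop("grid_dim must have length 3")
  if (ncol(X) > prod(grid_dim)) stop("grid too small for ncol(X) voxels")
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("subject_%03d", seq_len(nrow(X)))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"

  mask <- array(0, dim = grid_dim)
  mask[seq_len(ncol(X))] <- 1
  mask_path <- file.path(dir, paste0("mask", ext))
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)

  images <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    vol <- array(0, dim = grid_dim)
    vol[seq_len(ncol(X))] <- X[i, ]
    images[i] <- file.path(dir, paste0(subject_ids[i], ext))
    RNifti::writeNifti(RNifti::asNifti(vol), images[i])
  }
  invisible(list(mask = mask_path, images = images))
}
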