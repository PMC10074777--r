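#' Binary label volumes
#'
#' A `label_volume` pairs an [image_grid()] with a congruent 3D binary mask.
#' It is the common currency of the pipeline: contours are rasterized into
#' label volumes, and all metrics are computed from them.
#'
#' @param grid An [image_grid()].
#' @param voxels Logical (or 0/1 numeric) 3D array with `dim == grid$shape`.
#'   If omitted, an empty mask is created.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, voxels = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  if (is.null(voxels)) {
    voxels <- array(FALSE, dim = grid$shape)
  } else {
    if (!identical(dim(voxels), as.integer(grid$shape)))
      stop("mask dimensions must equal the grid shape", call. = FALSE)
    if (!is.logical(voxels)) {
      if (any(!voxels %in% c(0, 1)))
        stop("mask must be binary", call. = FALSE)
      voxels <- array(voxels != 0, dim = grid$shape)
    }
  }
  structure(list(grid = grid, voxels = voxels), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  n <- sum(x$voxels)
  cat(sprintf("<label_volume> %d set voxel(s) (%.4g c.c.) on ", n,
              n * voxel_volume_mm3(x$grid) / 1000))
  print(x$grid)
  invisible(x)
}

#' Total mask volume
#'
#' @param lv A [label_volume()].
#' @return Volume of the set voxels in c.c. (cm^3).
#' @export
mask_volume_cc <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  sum(lv$voxels) * voxel_volume_mm3(lv$grid) / 1000
}

#' Read a NIfTI label volume
#'
#' Nonzero voxels become the mask; grid geometry (spacing, origin,
#' direction) is taken from the NIfTI sform/qform.
#'
#' @param path Path to a `.nii` (or `.nii.gz`) file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("label-volume file not found: %s", path), call. = FALSE)
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a 3D image (dim: %s)", path,
                 paste(dim(arr), collapse = "x")), call. = FALSE)
  xf <- RNifti::xform(im, useQuaternionFirst = FALSE)
  aff <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(aff^2))
  direction <- sweep(aff, 2L, spacing, `/`)
  grid <- image_grid(dim(arr), spacing, origin = xf[1:3, 4],
                     direction = direction)
  label_volume(grid, arr != 0)
}

#' Write a NIfTI label volume
#'
#' @param lv A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  arr <- array(as.integer(lv$voxels), dim = lv$grid$shape)
  im <- RNifti::asNifti(arr)
  im <- RNifti::`pixdim<-`(im, lv$grid$spacing)
  xf <- diag(4)
  xf[1:3, 1:3] <- lv$grid$direction %*% diag(lv$grid$spacing)
  xf[1:3, 4] <- lv$grid$origin
  im <- RNifti::`sform<-`(im, structure(xf, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}
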