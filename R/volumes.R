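#' Three-class label volume
#'
#' A voxelized phantom ground truth: a 3D integer grid with values
#' 0 = air, 1 = adipose tissue, 2 = dense tissue, on an isotropic grid.
#' Axis convention: x = left-right (tube travel), y = posteroanterior with
#' the chest wall at y = 0, z = vertical with the breast support at z = 0.
#'
#' @param labels 3D integer array with values in \{0, 1, 2\}.
#' @param voxel_mm Isotropic voxel pitch in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_mm) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (!all(labels %in% 0:2))
    stop("labels must only contain values 0 (air), 1 (adipose), 2 (dense)")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0)
    stop("voxel_mm must be a positive scalar")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_mm = voxel_mm),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels at %.3f mm\n",
              d[1], d[2], d[3], x$voxel_mm))
  tab <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("  air %d | adipose %d | dense %d voxels\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Reconstruction volume
#'
#' Mean backprojected line-integral values on a 3D grid sharing the
#' `label_volume` frame (support at z = 0).
#'
#' @param values 3D numeric array.
#' @param voxel_mm Isotropic voxel pitch in mm.
#' @param coverage Optional integer array of the same shape counting how many
#'   projections covered each voxel (0 where no ray reached the detector).
#' @return An object of class `recon_volume`.
#' @export
recon_volume <- function(values, voxel_mm, coverage = NULL) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (any(!is.finite(values)))
    stop("values must be finite")
  if (!is.null(coverage) && !identical(dim(coverage), dim(values)))
    stop("coverage must match values in shape")
  structure(list(values = values, voxel_mm = voxel_mm, coverage = coverage),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("recon_volume: %d x %d x %d voxels at %.3f mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_mm, min(x$values), max(x$values)))
  invisible(x)
}

#' Write / read a label volume as NIfTI
#'
#' The voxel pitch is carried in the NIfTI pixdim header fields.
#'
#' @param v A `label_volume`.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(v, path) {
  stopifnot(inherits(v, "label_volume"))
  img <- RNifti::asNifti(v$labels)
  RNifti::pixdim(img) <- rep(v$voxel_mm, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(array(as.integer(round(img)), dim = dim(img)),
               voxel_mm = RNifti::pixdim(img)[1])
}

#' Write / read a reconstruction volume as NIfTI (float)
#'
#' @param v A `recon_volume`.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_recon_volume <- function(v, path) {
  stopifnot(inherits(v, "recon_volume"))
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- rep(v$voxel_mm, 3L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_recon_volume
#' @export
read_recon_volume <- function(path) {
  img <- RNifti::readNifti(path)
  recon_volume(array(as.numeric(img), dim = dim(img)),
               voxel_mm = RNifti::pixdim(img)[1])
}
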