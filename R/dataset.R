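#' Nearest-neighbor resampling of a label volume
#'
#' Resamples the categorical mask onto a new isotropic pitch (labels stay
#' categorical) and zero-pads with air to an optional target extent, so that
#' the mask becomes congruent with a reconstruction grid.
#'
#' @param mask A [label_volume()].
#' @param target_pitch_mm Target voxel pitch (mm).
#' @param target_dim Optional target grid size `c(nx, ny, nz)`; defaults to
#'   the resampled extent of the input.
#' @return A [label_volume()] at the target pitch.
#' @export
resample_mask <- function(mask, target_pitch_mm, target_dim = NULL) {
  stopifnot(inherits(mask, "label_volume"))
  if (target_pitch_mm <= 0) stop("target_pitch_mm must be positive")
  d <- dim(mask$labels)
  if (is.null(target_dim)) {
    if (target_pitch_mm == mask$voxel_mm)
      return(mask)
    target_dim <- pmax(1L, round(d * mask$voxel_mm / target_pitch_mm))
  }
  src_index <- function(n_t, axis) {
    centers <- (seq_len(n_t) - 0.5) * target_pitch_mm
    i <- floor(centers / mask$voxel_mm) + 1L
    ifelse(i >= 1L & i <= d[axis], i, NA_integer_)
  }
  ix <- src_index(target_dim[1], 1)
  iy <- src_index(target_dim[2], 2)
  iz <- src_index(target_dim[3], 3)
  padded <- array(0L, dim = d + 1L)  # extra air layer catches NA lookups
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask$labels
  ix[is.na(ix)] <- d[1] + 1L
  iy[is.na(iy)] <- d[2] + 1L
  iz[is.na(iz)] <- d[3] + 1L
  label_volume(padded[ix, iy, iz, drop = FALSE], target_pitch_mm)
}

#' Training/evaluation sample
#'
#' Pairs a reconstruction with its ground-truth mask on a congruent grid.
#'
#' @param recon A [recon_volume()].
#' @param mask A [label_volume()] with identical shape and pitch.
#' @param id Phantom identifier.
#' @param geometry_name Acquisition geometry the recon came from.
#' @return An object of class `vct_sample`.
#' @export
vct_sample <- function(recon, mask, id, geometry_name) {
  stopifnot(inherits(recon, "recon_volume"), inherits(mask, "label_volume"))
  if (!identical(dim(recon$values), dim(mask$labels)))
    stop("recon and mask grids are not congruent")
  if (abs(recon$voxel_mm - mask$voxel_mm) > 1e-9)
    stop("recon and mask pitches differ")
  structure(list(recon = recon, mask = mask, id = id,
                 geometry_name = geometry_name,
                 thickness = dim(mask$labels)[3]),
            class = "vct_sample")
}

# Integer block mean-pooling of a 3D array (crops trailing voxels so every
# block has k^3 members; the pooled mean then conserves the cropped mean).
pool_mean <- function(a, k) {
  d <- dim(a)
  nd <- d %/% k
  a <- a[seq_len(nd[1] * k), seq_len(nd[2] * k), seq_len(nd[3] * k),
         drop = FALSE]
  dim(a) <- c(k, nd[1], k, nd[2], k, nd[3])
  out <- colMeans(aperm(a, c(1, 3, 5, 2, 4, 6)), dims = 3)
  array(out, dim = nd)
}

# Nearest-neighbor pooling for labels: the block-center voxel.
pool_nn <- function(a, k) {
  d <- dim(a)
  nd <- d %/% k
  ctr <- function(n) (seq_len(n) - 1L) * k + as.integer(ceiling(k / 2))
  a[ctr(nd[1]), ctr(nd[2]), ctr(nd[3]), drop = FALSE]
}

#' Downsample a sample to a coarser grid
#'
#' Emulates the resolution-reduction step applied before network training:
#' the reconstruction is reduced by local-mean pooling and the mask by
#' nearest-neighbor (block-center) sampling, preserving the in-plane aspect
#' ratio and reducing the slice count proportionally. The pooling factor is
#' rounded to the nearest integer block size `k = round(1/factor)`;
#' trailing voxels that do not fill a block are cropped.
#'
#' @param sample A [vct_sample()].
#' @param factor Linear scale factor in (0, 1]; `1` is the identity.
#' @return A [vct_sample()] on the coarser grid.
#' @export
downsample_sample <- function(sample, factor = 0.2) {
  stopifnot(inherits(sample, "vct_sample"))
  if (!(factor > 0 && factor <= 1)) stop("factor must be in (0, 1]")
  k <- max(1L, as.integer(round(1 / factor)))
  if (k == 1L) return(sample)
  if (any(dim(sample$mask$labels) %/% k < 8L))
    stop("downsampling would leave a dimension below 8 voxels")
  new_pitch <- sample$recon$voxel_mm * k
  rec <- recon_volume(pool_mean(sample$recon$values, k), new_pitch)
  msk <- label_volume(pool_nn(sample$mask$labels, k), new_pitch)
  vct_sample(rec, msk, sample$id, sample$geometry_name)
}

#' Write a set of samples as paired NIfTI files with a CSV manifest
#'
#' @param samples List of [vct_sample()] objects.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    stem <- sprintf("%s_%s", s$id, s$geometry_name)
    write_recon_volume(s$recon, file.path(dir, paste0(stem, "_recon.nii.gz")))
    write_label_volume(s$mask, file.path(dir, paste0(stem, "_mask.nii.gz")))
    d <- dim(s$mask$labels)
    data.frame(id = s$id, geometry = s$geometry_name,
               nx = d[1], ny = d[2], nz = d[3],
               voxel_mm = s$mask$voxel_mm, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_samples
#' @export
read_samples <- function(dir) {
  # geometry "T" must not be parsed as logical TRUE
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(id = "character",
                                             geometry = "character"))
  lapply(seq_len(nrow(manifest)), function(i) {
    stem <- sprintf("%s_%s", manifest$id[i], manifest$geometry[i])
    vct_sample(
      read_recon_volume(file.path(dir, paste0(stem, "_recon.nii.gz"))),
      read_label_volume(file.path(dir, paste0(stem, "_mask.nii.gz"))),
      manifest$id[i], manifest$geometry[i])
  })
}
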