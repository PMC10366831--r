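#' Unfiltered simple backprojection
#'
#' Voxel-driven backprojection: for every voxel and every source, the ray
#' from the source through the voxel center is intersected with the detector
#' plane and the projection image is sampled there by bilinear
#' interpolation. The voxel value is the mean over the projections whose
#' detector intersection fell inside the panel; no filtering is applied.
#' Voxels covered by no projection are zero and flagged in the coverage
#' mask.
#'
#' @param p A `projection_set` (one image per source).
#' @param geometry Acquisition geometry; defaults to the one stored in `p`.
#' @param grid_dim Reconstruction grid size `c(nx, ny, nz)` (voxels).
#' @param voxel_mm Reconstruction voxel pitch (mm).
#' @return A [recon_volume()] with a `coverage` count array.
#' @export
backproject <- function(p, geometry = p$geometry, grid_dim, voxel_mm) {
  stopifnot(inherits(p, "projection_set"))
  det <- geometry$detector
  if (dim(p$images)[3] != nrow(geometry$sources))
    stop("projection set and geometry disagree on the number of sources")
  org <- volume_origin(grid_dim, voxel_mm, det)
  nx <- grid_dim[1]; ny <- grid_dim[2]; nz <- grid_dim[3]
  xc <- org[1] + (seq_len(nx) - 0.5) * voxel_mm
  yc <- org[2] + (seq_len(ny) - 0.5) * voxel_mm
  zc <- org[3] + (seq_len(nz) - 0.5) * voxel_mm
  X <- rep(xc, times = ny * nz)
  Y <- rep(rep(yc, each = nx), times = nz)
  Z <- rep(zc, each = nx * ny)
  zdet <- -det$gap_mm
  acc <- numeric(nx * ny * nz)
  cov <- integer(nx * ny * nz)
  for (s in seq_len(nrow(geometry$sources))) {
    sp <- geometry$sources[s, ]
    tpar <- (zdet - sp[3]) / (Z - sp[3])
    xd <- sp[1] + (X - sp[1]) * tpar
    yd <- sp[2] + (Y - sp[2]) * tpar
    # continuous pixel-index coordinates: pixel k is centered at uc = k
    uc <- xd / det$pixel_pitch_mm + 0.5
    vc <- yd / det$pixel_pitch_mm + 0.5
    i0 <- as.integer(floor(uc))  # pixel index of the lower neighbor
    j0 <- as.integer(floor(vc))
    fu <- uc - i0
    fv <- vc - j0
    ok <- i0 >= 1L & i0 + 1L <= det$n_u & j0 >= 1L & j0 + 1L <= det$n_v
    if (!any(ok)) next
    img <- p$images[, , s]
    idx <- function(i, j) (j - 1L) * det$n_u + i
    val <- numeric(length(acc))
    io <- i0[ok]; jo <- j0[ok]; fuo <- fu[ok]; fvo <- fv[ok]
    val[ok] <-
      img[idx(io,      jo)]      * (1 - fuo) * (1 - fvo) +
      img[idx(io + 1L, jo)]      * fuo       * (1 - fvo) +
      img[idx(io,      jo + 1L)] * (1 - fuo) * fvo +
      img[idx(io + 1L, jo + 1L)] * fuo       * fvo
    acc <- acc + val
    cov <- cov + ok
  }
  vals <- ifelse(cov > 0L, acc / pmax(cov, 1L), 0)
  recon_volume(array(vals, dim = grid_dim), voxel_mm,
               coverage = array(cov, dim = grid_dim))
}

#' Full width at half maximum of the z point-spread profile
#'
#' Quantifies the out-of-plane (limited-angle) artifact: the FWHM of the
#' z-profile through the global maximum of a point reconstruction, with the
#' half-maximum crossings located by linear interpolation.
#'
#' @param recon A [recon_volume()] containing a single dominant peak.
#' @return FWHM in mm.
#' @export
zpsf_width <- function(recon) {
  stopifnot(inherits(recon, "recon_volume"))
  v <- recon$values
  if (max(v) <= min(v)) stop("flat profile: no peak to measure")
  pk <- arrayInd(which.max(v), dim(v))
  prof <- v[pk[1], pk[2], ]
  half <- (max(prof) + min(prof)) / 2
  iz <- which.max(prof)
  # walk outward from the peak to the first half-maximum crossing each side
  cross <- function(dir) {
    i <- iz
    while (i + dir >= 1 && i + dir <= length(prof) && prof[i + dir] > half)
      i <- i + dir
    j <- i + dir
    if (j < 1 || j > length(prof)) return(abs(i - iz) + 0.5)
    frac <- (prof[i] - half) / (prof[i] - prof[j])
    abs(i - iz) + frac
  }
  (cross(-1L) + cross(1L)) * recon$voxel_mm
}

#' Threshold-based air/tissue segmentation of a reconstruction
#'
#' Backprojected values in an unfiltered reconstruction fall into three
#' regimes: air background (near zero), the smeared breast-boundary band
#' (columns with a short tissue path, including the convex-hull gap), and
#' interior tissue. The values are clustered with `stats::kmeans` (three
#' centers) and the air/tissue threshold is placed at the midpoint of the
#' two lowest centers, so any column carrying tissue signal counts as
#' tissue — the decision a reader of the reconstruction would make. Used
#' to expose the convex-hull artifact without any trained model.
#'
#' @param recon A [recon_volume()].
#' @param max_sample Cap on the number of voxels used to fit the threshold.
#' @return A [label_volume()] with classes \{0 = air, 1 = tissue\}.
#' @export
segment_air_threshold <- function(recon, max_sample = 50000L) {
  stopifnot(inherits(recon, "recon_volume"))
  v <- as.numeric(recon$values)
  set.seed(0L)
  samp <- if (length(v) > max_sample) sample(v, max_sample) else v
  km <- stats::kmeans(samp, centers = 3L, nstart = 5L)
  ctrs <- sort(km$centers)
  thr <- mean(ctrs[1:2])
  label_volume(array(as.integer(recon$values >= thr), dim(recon$values)),
               recon$voxel_mm)
}
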