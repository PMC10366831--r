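#' Population specification for phantom sampling
#'
#' Describes the screening population the virtual cohort is matched to:
#' compressed breast thickness (CBT) and volumetric breast density (%VBD),
#' each summarized by median and interquartile range. Defaults reproduce the
#' demographics of a screening cohort (CBT median 60.50 mm, IQR 51.50-69.5;
#' %VBD median 12.75, IQR 8.40-20.00). Both quantities are positive and
#' right-skewed, so samples are drawn from log-normal distributions fitted to
#' the median and IQR; CBT is additionally capped (default 85 mm, the
#' maximum thickness the outline model supports).
#'
#' @param n_phantoms Number of phantoms to sample (>= 1).
#' @param cbt_median_mm,cbt_q1_mm,cbt_q3_mm CBT median and quartiles (mm).
#' @param vbd_median_pct,vbd_q1_pct,vbd_q3_pct %VBD median and quartiles.
#' @param cbt_cap_mm Maximum simulated thickness (mm); samples are clipped.
#' @param voxel_mm Isotropic voxel pitch for generated phantoms (mm).
#' @param seed RNG seed for reproducible sampling.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_phantoms,
                            cbt_median_mm = 60.50, cbt_q1_mm = 51.50,
                            cbt_q3_mm = 69.5,
                            vbd_median_pct = 12.75, vbd_q1_pct = 8.40,
                            vbd_q3_pct = 20.00,
                            cbt_cap_mm = 85, voxel_mm = 0.5, seed = 1L) {
  if (!is.numeric(n_phantoms) || n_phantoms < 1)
    stop("n_phantoms must be >= 1")
  check_quartiles <- function(q1, med, q3, what) {
    if (!(q1 < med && med < q3))
      stop(sprintf("%s quartiles must satisfy q1 < median < q3", what))
  }
  check_quartiles(cbt_q1_mm, cbt_median_mm, cbt_q3_mm, "CBT")
  check_quartiles(vbd_q1_pct, vbd_median_pct, vbd_q3_pct, "%VBD")
  if (cbt_q1_mm <= 0 || vbd_q1_pct <= 0)
    stop("quartiles must be positive")
  structure(list(n_phantoms = as.integer(n_phantoms),
                 cbt_median_mm = cbt_median_mm, cbt_q1_mm = cbt_q1_mm,
                 cbt_q3_mm = cbt_q3_mm,
                 vbd_median_pct = vbd_median_pct, vbd_q1_pct = vbd_q1_pct,
                 vbd_q3_pct = vbd_q3_pct,
                 cbt_cap_mm = cbt_cap_mm, voxel_mm = voxel_mm,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# log-normal parameters matched to (median, q1, q3): the median fixes meanlog,
# the IQR on the log scale fixes sdlog.
lognormal_from_quartiles <- function(median, q1, q3) {
  list(meanlog = log(median),
       sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Compressed-breast outline parameters
#'
#' Parametric surrogate of the compressed breast: flat vertical boundary in
#' the bands contacting the compression paddle (top) and support (bottom),
#' with a superelliptic lateral bulge in between (maximal overhang at
#' mid-thickness). Every horizontal slice footprint is a half-ellipse
#' attached to the chest-wall plane y = 0.
#'
#' @param cbt_mm Compressed breast thickness: support (z = 0) to paddle.
#' @param cnd_mm Chest-to-nipple distance: extent along the PA axis (mm).
#' @param width_mm Left-right extent at the chest wall (mm).
#' @param contact_fraction Fraction of the thickness in flat contact with the
#'   paddle and support combined (half at each face); in (0, 1].
#' @param bulge_mm Maximal lateral overhang of the curved free surface (mm).
#' @param curvature_exponent Shape exponent of the superelliptic bulge
#'   profile (2 = elliptic; larger = flatter mid-section).
#' @return An object of class `outline_params`.
#' @export
outline_params <- function(cbt_mm, cnd_mm, width_mm,
                           contact_fraction = 0.4, bulge_mm = 0,
                           curvature_exponent = 2) {
  if (cbt_mm <= 0 || cnd_mm <= 0 || width_mm <= 0)
    stop("cbt_mm, cnd_mm and width_mm must be positive")
  if (!(contact_fraction > 0 && contact_fraction <= 1))
    stop("contact_fraction must be in (0, 1]")
  if (bulge_mm < 0) stop("bulge_mm must be >= 0")
  if (curvature_exponent <= 0) stop("curvature_exponent must be positive")
  structure(list(cbt_mm = cbt_mm, cnd_mm = cnd_mm, width_mm = width_mm,
                 contact_fraction = contact_fraction, bulge_mm = bulge_mm,
                 curvature_exponent = curvature_exponent),
            class = "outline_params")
}

#' Sample a virtual population of outline parameters and density targets
#'
#' Draws `n_phantoms` (CBT, %VBD) pairs from log-normal distributions
#' calibrated to the population's median/IQR, caps CBT at `cbt_cap_mm`, and derives
#' the remaining outline parameters from CBT with fixed anthropometric
#' ratios (chest-to-nipple distance about 1.75 x CBT, width about 1.3 x CND,
#' bulge about 0.15 x CBT).
#'
#' @param spec A [population_spec()].
#' @param cnd_ratio,width_ratio,bulge_ratio,contact_fraction,curvature_exponent
#'   Anthropometric ratios tying the remaining outline parameters to CBT.
#' @return A data.frame (class `population_sample`) with one row per phantom:
#'   `id`, `cbt_mm` (capped), `cbt_raw_mm` (pre-cap), `cnd_mm`, `width_mm`,
#'   `bulge_mm`, `contact_fraction`, `curvature_exponent`, `target_vbd`
#'   (fraction), and a per-phantom `seed`.
#' @export
sample_population <- function(spec, cnd_ratio = 1.75, width_ratio = 1.3,
                              bulge_ratio = 0.15, contact_fraction = 0.4,
                              curvature_exponent = 2) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_phantoms
  cbt_par <- lognormal_from_quartiles(spec$cbt_median_mm, spec$cbt_q1_mm,
                                      spec$cbt_q3_mm)
  vbd_par <- lognormal_from_quartiles(spec$vbd_median_pct, spec$vbd_q1_pct,
                                      spec$vbd_q3_pct)
  cbt_raw <- stats::rlnorm(n, cbt_par$meanlog, cbt_par$sdlog)
  cbt <- pmin(cbt_raw, spec$cbt_cap_mm)
  vbd <- stats::rlnorm(n, vbd_par$meanlog, vbd_par$sdlog) / 100
  vbd <- pmin(vbd, 0.95)  # guard: a density fraction, not a percentage
  out <- data.frame(
    id = sprintf("phantom%03d", seq_len(n)),
    cbt_mm = cbt,
    cbt_raw_mm = cbt_raw,
    cnd_mm = cnd_ratio * cbt,
    width_mm = width_ratio * cnd_ratio * cbt,
    bulge_mm = bulge_ratio * cbt,
    contact_fraction = contact_fraction,
    curvature_exponent = curvature_exponent,
    target_vbd = vbd,
    seed = spec$seed + seq_len(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("population_sample", "data.frame")
  out
}

#' @rdname sample_population
#' @param row One row of a `population_sample` data.frame.
#' @export
outline_from_row <- function(row) {
  outline_params(cbt_mm = row$cbt_mm, cnd_mm = row$cnd_mm,
                 width_mm = row$width_mm,
                 contact_fraction = row$contact_fraction,
                 bulge_mm = row$bulge_mm,
                 curvature_exponent = row$curvature_exponent)
}

# Normalized bulge profile s(z) in [0, 1]: zero in the flat contact bands,
# superelliptic in between, maximal (1) at mid-thickness.
bulge_profile <- function(z, cbt, contact_fraction, exponent) {
  lo <- contact_fraction / 2 * cbt
  hi <- cbt - lo
  s <- numeric(length(z))
  inside <- z > lo & z < hi
  if (hi > lo && any(inside)) {
    u <- (z[inside] - lo) / (hi - lo)
    s[inside] <- (1 - abs(2 * u - 1)^exponent)^(1 / exponent)
  }
  s
}

#' Voxelize a compressed-breast outline
#'
#' Rasterizes the parametric outline onto an isotropic grid. Slice
#' footprints are half-ellipses attached to the chest wall (y = 0) whose
#' semi-axes grow by `bulge_mm * s(z)` where `s` is the superelliptic bulge
#' profile; the footprint area is therefore maximal at mid-thickness and
#' non-increasing toward the paddle and support faces.
#'
#' @param p An [outline_params()].
#' @param voxel_mm Isotropic voxel pitch (mm).
#' @param nx,ny Optional in-plane grid size (voxels); defaults fit the
#'   outline with a one-voxel air margin laterally.
#' @return A logical 3D array (`TRUE` = tissue) with attribute `voxel_mm`.
#' @export
generate_outline <- function(p, voxel_mm, nx = NULL, ny = NULL) {
  stopifnot(inherits(p, "outline_params"))
  nz <- round(p$cbt_mm / voxel_mm)
  if (nz < 3)
    stop("cbt_mm must span at least 3 voxels at this pitch")
  if (is.null(nx))
    nx <- ceiling((p$width_mm + 2 * p$bulge_mm) / voxel_mm) + 2L
  if (is.null(ny))
    ny <- ceiling((p$cnd_mm + p$bulge_mm) / voxel_mm) + 1L
  cx <- nx * voxel_mm / 2
  xc <- (seq_len(nx) - 0.5) * voxel_mm
  yc <- (seq_len(ny) - 0.5) * voxel_mm
  zc <- (seq_len(nz) - 0.5) * voxel_mm
  s <- bulge_profile(zc, p$cbt_mm, p$contact_fraction, p$curvature_exponent)
  mask <- array(FALSE, dim = c(nx, ny, nz))
  for (iz in seq_len(nz)) {
    a <- p$width_mm / 2 + p$bulge_mm * s[iz]
    b <- p$cnd_mm + p$bulge_mm * s[iz]
    mask[, , iz] <- outer(((xc - cx) / a)^2, (yc / b)^2, "+") <= 1
  }
  attr(mask, "voxel_mm") <- voxel_mm
  mask
}

# O(1) block sums of a 3D 0/1 array via an inclusive cumulative sum table.
cumsum3d <- function(a) {
  s <- apply(a, c(2, 3), cumsum)
  s <- aperm(apply(s, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(s, c(1, 2), cumsum), c(2, 3, 1))
}

block_sum <- function(S, x0, x1, y0, y1, z0, z1) {
  # sum of a[x0:x1, y0:y1, z0:z1] with x0 etc. >= 1
  g <- function(i, j, k) if (i < 1 || j < 1 || k < 1) 0 else S[i, j, k]
  g(x1, y1, z1) - g(x0 - 1, y1, z1) - g(x1, y0 - 1, z1) - g(x1, y1, z0 - 1) +
    g(x0 - 1, y0 - 1, z1) + g(x0 - 1, y1, z0 - 1) + g(x1, y0 - 1, z0 - 1) -
    g(x0 - 1, y0 - 1, z0 - 1)
}

#' Fill a tissue mask with dense tissue by octree subdivision
#'
#' Recursively subdivides the tissue region into octants down to
#' `min_block_mm` and assigns whole blocks to dense tissue, in seeded random
#' order, until the achieved dense fraction is within +/- 0.5 percentage
#' points of `target_vbd`; the remaining tissue is adipose. If the target is
#' unreachable at the block granularity the nearest achievable fraction is
#' used with a warning.
#'
#' @param mask Logical 3D tissue mask (from [generate_outline()]).
#' @param target_vbd Target volumetric dense fraction, in (0, 1); values at
#'   or below the voxel granularity yield an all-adipose volume.
#' @param voxel_mm Voxel pitch of `mask` (mm); defaults to its attribute.
#' @param min_block_mm Smallest octree block edge (mm); default one voxel.
#' @param max_block_mm Largest block assigned whole (mm); larger candidate
#'   blocks are always subdivided first. Bounds the size of individual
#'   dense structures (default 15 mm, a coarse fibroglandular scale).
#' @param seed RNG seed controlling block placement.
#' @param tol_vbd Acceptable deviation of the achieved fraction (default
#'   0.005, i.e. half a percentage point).
#' @return A [label_volume()].
#' @export
fill_tissue <- function(mask, target_vbd, voxel_mm = attr(mask, "voxel_mm"),
                        min_block_mm = voxel_mm, max_block_mm = 15,
                        seed = 1L, tol_vbd = 0.005) {
  if (is.null(voxel_mm)) stop("voxel_mm must be supplied")
  if (!(target_vbd >= 0 && target_vbd < 1))
    stop("target_vbd must be in [0, 1)")
  set.seed(seed)
  labels <- array(0L, dim = dim(mask))
  labels[mask] <- 1L
  n_tissue <- sum(mask)
  if (n_tissue == 0L) stop("mask contains no tissue")
  target_count <- round(target_vbd * n_tissue)
  if (target_count == 0L)
    return(label_volume(labels, voxel_mm))

  min_block_vox <- max(1L, round(min_block_mm / voxel_mm))
  max_block_vox <- max(min_block_vox, round(max_block_mm / voxel_mm))
  S <- cumsum3d(mask * 1L)
  d <- dim(mask)
  # top-level blocks: cubes of edge 2^k * min_block covering the grid
  top <- min_block_vox
  while (top * 2 < max(d)) top <- top * 2L

  remaining <- target_count
  assign_block <- function(x0, y0, z0, size) {
    x1 <- min(x0 + size - 1L, d[1]); y1 <- min(y0 + size - 1L, d[2])
    z1 <- min(z0 + size - 1L, d[3])
    sub <- mask[x0:x1, y0:y1, z0:z1, drop = FALSE] &
      labels[x0:x1, y0:y1, z0:z1, drop = FALSE] == 1L
    labels[x0:x1, y0:y1, z0:z1][sub] <<- 2L
    remaining <<- remaining - sum(sub)
  }
  visit <- function(x0, y0, z0, size) {
    if (remaining <= 0L) return(invisible())
    if (x0 > d[1] || y0 > d[2] || z0 > d[3]) return(invisible())
    cnt <- block_sum(S, x0, min(x0 + size - 1L, d[1]),
                     y0, min(y0 + size - 1L, d[2]),
                     z0, min(z0 + size - 1L, d[3]))
    if (cnt == 0) return(invisible())
    if (size > max_block_vox && size > min_block_vox) {
      h <- size %/% 2L
      offs <- expand.grid(dx = c(0L, h), dy = c(0L, h), dz = c(0L, h))
      for (i in sample(nrow(offs)))
        visit(x0 + offs$dx[i], y0 + offs$dy[i], z0 + offs$dz[i], h)
    } else if (cnt <= remaining) {
      assign_block(x0, y0, z0, size)
    } else if (size > min_block_vox) {
      h <- size %/% 2L
      offs <- expand.grid(dx = c(0L, h), dy = c(0L, h), dz = c(0L, h))
      for (i in sample(nrow(offs))) {
        visit(x0 + offs$dx[i], y0 + offs$dy[i], z0 + offs$dz[i], h)
      }
    } else if (cnt < 2L * remaining) {
      # minimal block overshoots but lands closer to the target than skipping
      assign_block(x0, y0, z0, size)
    }
  }
  starts <- expand.grid(x = seq(1L, d[1], by = top),
                        y = seq(1L, d[2], by = top),
                        z = seq(1L, d[3], by = top))
  for (i in sample(nrow(starts)))
    visit(starts$x[i], starts$y[i], starts$z[i], top)

  achieved <- sum(labels == 2L) / n_tissue
  if (abs(achieved - target_vbd) > tol_vbd)
    warning(sprintf(
      "target VBD %.4f unreachable at block granularity; achieved %.4f",
      target_vbd, achieved))
  label_volume(labels, voxel_mm)
}

#' Measure volumetric breast density
#'
#' The dense-tissue fraction of the breast: dense voxels divided by total
#' tissue (dense + adipose) voxels.
#'
#' @param v A [label_volume()].
#' @return The VBD as a fraction in \[0, 1\].
#' @export
measure_vbd <- function(v) {
  stopifnot(inherits(v, "label_volume"))
  n_dense <- sum(v$labels == 2L)
  n_adipose <- sum(v$labels == 1L)
  if (n_dense + n_adipose == 0L)
    stop("volume contains no tissue voxels")
  n_dense / (n_dense + n_adipose)
}

#' Generate one full phantom from a population row
#'
#' Convenience wrapper: voxelizes the outline and fills it with dense tissue
#' at the row's target VBD.
#'
#' @param row One row of [sample_population()] output.
#' @param voxel_mm Voxel pitch (mm).
#' @param nx,ny Optional in-plane grid size passed to [generate_outline()].
#' @return A [label_volume()].
#' @export
generate_phantom <- function(row, voxel_mm, nx = NULL, ny = NULL) {
  mask <- generate_outline(outline_from_row(row), voxel_mm, nx = nx, ny = ny)
  fill_tissue(mask, row$target_vbd, voxel_mm = voxel_mm, seed = row$seed)
}
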