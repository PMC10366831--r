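#' Linear attenuation coefficients of the phantom materials
#'
#' Monoenergetic effective-energy model. Defaults are tabulated ICRU Report
#' 44 tissue compositions at 20 keV: adipose tissue about 0.054 / mm and
#' breast glandular (dense) tissue about 0.080 / mm; air is treated as
#' non-attenuating at mammographic energies.
#'
#' @param mu_air,mu_adipose,mu_dense Linear attenuation coefficients (1/mm).
#' @param energy_kev Stated effective energy (metadata only).
#' @return An object of class `material_table`.
#' @export
material_table <- function(mu_air = 0, mu_adipose = 0.0540,
                           mu_dense = 0.0802, energy_kev = 20) {
  if (!(mu_air >= 0 && mu_air < mu_adipose && mu_adipose < mu_dense))
    stop("need 0 <= mu_air < mu_adipose < mu_dense")
  structure(list(mu_air = mu_air, mu_adipose = mu_adipose,
                 mu_dense = mu_dense, energy_kev = energy_kev),
            class = "material_table")
}

mu_lookup <- function(materials) {
  c(materials$mu_air, materials$mu_adipose, materials$mu_dense)
}

# World placement of a volume relative to a detector: the volume's x extent
# is centered on the detector's, the chest wall (y = 0) coincides with the
# detector edge, and the support plane z = 0 sits gap_mm above the detector.
volume_origin <- function(volume_dim, voxel_mm, detector) {
  c(x = (detector$n_u * detector$pixel_pitch_mm - volume_dim[1] * voxel_mm) / 2,
    y = 0, z = 0)
}

#' Line integral of attenuation along one ray
#'
#' Exact Siddon-style traversal of a piecewise-constant label volume:
#' the sum of mu(voxel) times the ray-voxel intersection length between
#' `src` and `dst` (dimensionless).
#'
#' @param volume A [label_volume()].
#' @param materials A [material_table()].
#' @param src,dst Ray endpoints, numeric xyz in the volume frame (mm);
#'   `src` must lie outside the volume.
#' @param origin World position of the volume's (0,0,0) corner (mm).
#' @return The line integral (a non-negative scalar).
#' @export
ray_integral <- function(volume, materials, src, dst, origin = c(0, 0, 0)) {
  stopifnot(inherits(volume, "label_volume"))
  d <- dim(volume$labels)
  lo <- origin
  hi <- origin + d * volume$voxel_mm
  if (all(src > lo & src < hi))
    stop("src must lie outside the volume")
  mu <- mu_lookup(materials)[volume$labels + 1L]
  dim(mu) <- d
  siddon_ray_cpp(mu, volume$voxel_mm, as.numeric(origin),
                 as.numeric(src), as.numeric(dst))
}

#' Cone-beam forward projection of a label volume
#'
#' Casts one ray per detector pixel center from each source position and
#' records the attenuation line integral (noiseless, deterministic).
#'
#' @param volume A [label_volume()]; must fit between support and paddle
#'   (i.e. below every source).
#' @param geometry An `acq_geometry`.
#' @param materials A [material_table()].
#' @return An object of class `projection_set`: `images` is an array
#'   `(n_u, n_v, n_sources)` of line integrals, plus the geometry and noise
#'   metadata (`"noiseless"`).
#' @export
forward_project <- function(volume, geometry, materials = material_table()) {
  stopifnot(inherits(volume, "label_volume"),
            inherits(geometry, "acq_geometry"))
  det <- geometry$detector
  d <- dim(volume$labels)
  top <- d[3] * volume$voxel_mm
  if (any(geometry$sources[, "z"] <= top))
    stop("geometry/volume frame mismatch: sources must be above the volume")
  org <- volume_origin(d, volume$voxel_mm, det)
  mu <- mu_lookup(materials)[volume$labels + 1L]
  dim(mu) <- d
  img <- siddon_project_cpp(mu, volume$voxel_mm, as.numeric(org),
                            geometry$sources,
                            det$pixel_pitch_mm, det$n_u, det$n_v,
                            -det$gap_mm)
  structure(list(images = img, geometry = geometry, noise = "noiseless"),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("projection_set: %d projections of %d x %d pixels (%s)\n",
              d[3], d[1], d[2],
              if (identical(x$noise, "noiseless")) "noiseless"
              else "Poisson noise"))
  invisible(x)
}

#' Add exposure-scaled Poisson noise to projections
#'
#' Models photon-counting noise: transmitted counts per pixel are drawn as
#' Poisson(fluence_per_mAs * exposure_scale * exp(-line integral)) and
#' converted back to noisy line integrals. Zero-count pixels are floored at
#' one count to keep the log finite.
#'
#' @param p A `projection_set`.
#' @param fluence_per_mAs Mean incident photon count per pixel at unit
#'   exposure; must be positive.
#' @param exposure_scale Relative total exposure; defaults to the
#'   geometry's (1 for conventional/T, 6 for XWR).
#' @param seed RNG seed.
#' @return A new `projection_set` with noisy line integrals.
#' @export
add_noise <- function(p, fluence_per_mAs, exposure_scale = NULL, seed = 1L) {
  stopifnot(inherits(p, "projection_set"))
  if (fluence_per_mAs <= 0) stop("fluence_per_mAs must be positive")
  if (is.null(exposure_scale)) exposure_scale <- p$geometry$exposure_scale
  set.seed(seed)
  i0 <- fluence_per_mAs * exposure_scale
  lambda <- i0 * exp(-p$images)
  big <- lambda > 1e9  # Gaussian limit where rpois would overflow
  counts <- numeric(length(lambda))
  counts[!big] <- stats::rpois(sum(!big), lambda[!big])
  counts[big] <- stats::rnorm(sum(big), lambda[big], sqrt(lambda[big]))
  counts <- pmax(counts, 1)
  noisy <- array(-log(counts / i0), dim = dim(p$images))
  structure(list(images = noisy, geometry = p$geometry,
                 noise = list(fluence_per_mAs = fluence_per_mAs,
                              exposure_scale = exposure_scale, seed = seed)),
            class = "projection_set")
}

#' Write / read a projection set (multi-page TIFF + JSON sidecar)
#'
#' @param p A `projection_set`.
#' @param path Output TIFF file; the sidecar is written at `<path>.json`.
#' @return `path` invisibly; `read_projection_set()` returns the set.
#' @export
write_projection_set <- function(p, path) {
  stopifnot(inherits(p, "projection_set"))
  pages <- lapply(seq_len(dim(p$images)[3]),
                  function(k) t(p$images[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  side <- list(noise = p$noise, geometry_name = p$geometry$name)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_geometry(p$geometry, paste0(path, ".geom.json"))
  invisible(path)
}

#' @rdname write_projection_set
#' @export
read_projection_set <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  img <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) img[, , k] <- t(pages[[k]])
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- read_geometry(paste0(path, ".geom.json"))
  structure(list(images = img, geometry = geom, noise = side$noise),
            class = "projection_set")
}
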