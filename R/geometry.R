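#' Detector specification
#'
#' Flat-panel detector in the plane z = -gap_mm, immediately below the
#' breast support. Pixels are indexed u along x (left-right) and v along y
#' (posteroanterior, chest wall at y = 0). The default desk-scale detector
#' keeps the clinical width-to-height aspect ratio of 0.79 (n_v / n_u).
#'
#' @param pixel_pitch_mm Square pixel pitch (mm).
#' @param n_u Pixel count along x.
#' @param n_v Pixel count along y.
#' @param gap_mm Air gap between the support plane (z = 0) and the detector.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(pixel_pitch_mm = 2.5, n_u = 122L, n_v = 96L,
                          gap_mm = 25) {
  if (pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be positive")
  if (n_u < 1 || n_v < 1) stop("detector needs at least one pixel per axis")
  if (gap_mm < 0) stop("gap_mm must be >= 0")
  structure(list(pixel_pitch_mm = pixel_pitch_mm,
                 n_u = as.integer(n_u), n_v = as.integer(n_v),
                 gap_mm = gap_mm),
            class = "detector_spec")
}

detector_center <- function(det) {
  c(x = det$n_u * det$pixel_pitch_mm / 2,
    y = det$n_v * det$pixel_pitch_mm / 2)
}

new_geometry <- function(name, sources, motion, detector, exposure_scale,
                         sid_mm = NA_real_, radius_mm = NA_real_) {
  stopifnot(inherits(detector, "detector_spec"))
  sources <- matrix(as.numeric(sources), ncol = 3L,
                    dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(sources) < 1L) stop("geometry needs at least one source")
  if (any(sources[, "z"] <= 0))
    stop("all sources must lie above the support plane")
  if (exposure_scale <= 0) stop("exposure_scale must be positive")
  structure(list(name = name, sources = sources, motion = motion,
                 detector = detector, exposure_scale = exposure_scale,
                 sid_mm = sid_mm, radius_mm = radius_mm),
            class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf("acq_geometry '%s': %d sources (%s), exposure scale %g\n",
              x$name, nrow(x$sources), x$motion, x$exposure_scale))
  invisible(x)
}

# Equal-step angle grid over [-half, +half]; a single view sits on axis.
angle_grid <- function(n, half_angle_deg) {
  if (n == 1L) return(0)
  seq(-half_angle_deg, half_angle_deg, length.out = n) * pi / 180
}

#' Conventional DBT geometry: linear left-right scan
#'
#' `n` source positions at constant height `sid_mm` above the support, with
#' the focal spot translating left-right so the extreme positions subtend
#' +/- `half_angle_deg` at the detector-center pivot.
#'
#' @param n Number of projections (default 15).
#' @param half_angle_deg Half angular range in degrees (default 7.5).
#' @param sid_mm Source-to-support distance for the linear scan (mm).
#' @param detector A [detector_spec()].
#' @return An `acq_geometry`.
#' @export
make_conventional <- function(n = 15L, half_angle_deg = 7.5, sid_mm = 620,
                              detector = detector_spec()) {
  if (n < 1) stop("n must be >= 1")
  if (half_angle_deg <= 0) stop("half_angle_deg must be positive")
  ctr <- detector_center(detector)
  th <- angle_grid(as.integer(n), half_angle_deg)
  src <- cbind(ctr["x"] + sid_mm * tan(th), ctr["y"], sid_mm)
  new_geometry("conventional", src, "linear_LR", detector,
               exposure_scale = 1, sid_mm = sid_mm)
}

#' T-shaped DBT geometry: bidirectional linear scan
#'
#' Two orthogonal linear legs forming a "T": `n_lr` positions translating
#' left-right (as in the conventional scan) followed by `n_pa` positions
#' translating posteroanteriorly at the central x. Defaults give the
#' 8 LR + 7 PA = 15 projections of the T acquisition.
#'
#' @param n_pa Number of PA-leg projections (default 7).
#' @param n_lr Number of LR-leg projections (default 8).
#' @inheritParams make_conventional
#' @return An `acq_geometry`.
#' @export
make_t <- function(n_pa = 7L, n_lr = 8L, half_angle_deg = 7.5, sid_mm = 620,
                   detector = detector_spec()) {
  if (n_pa < 1 || n_lr < 1)
    stop("both legs of the T need at least one projection")
  ctr <- detector_center(detector)
  th_lr <- angle_grid(as.integer(n_lr), half_angle_deg)
  th_pa <- angle_grid(as.integer(n_pa), half_angle_deg)
  src <- rbind(
    cbind(ctr["x"] + sid_mm * tan(th_lr), ctr["y"], sid_mm),
    cbind(ctr["x"], ctr["y"] + sid_mm * tan(th_pa), sid_mm)
  )
  new_geometry("T", src, "linear_LR+PA", detector,
               exposure_scale = 1, sid_mm = sid_mm)
}

#' Extra-wide-range (XWR) DBT geometry: arc scan
#'
#' `n` sources on a circular arc of radius `radius_mm` in the x-z plane,
#' pivoting about the breast-support plane at the detector center, spanning
#' +/- `half_angle_deg`. Total exposure is 6x the conventional scan.
#'
#' @param n Number of projections (default 91).
#' @param half_angle_deg Half angular range (default 45).
#' @param radius_mm Arc radius (default 738 mm).
#' @param detector A [detector_spec()].
#' @return An `acq_geometry`.
#' @export
make_xwr <- function(n = 91L, half_angle_deg = 45, radius_mm = 738,
                     detector = detector_spec()) {
  if (n < 2) stop("an arc needs at least 2 sources")
  if (radius_mm <= detector$gap_mm)
    stop("radius_mm must exceed the detector gap")
  ctr <- detector_center(detector)
  th <- angle_grid(as.integer(n), half_angle_deg)
  src <- cbind(ctr["x"] + radius_mm * sin(th), ctr["y"],
               radius_mm * cos(th))
  new_geometry("XWR", src, "arc_LR", detector,
               exposure_scale = 6, radius_mm = radius_mm)
}

#' Serialize / deserialize an acquisition geometry as JSON
#'
#' @param g An `acq_geometry`.
#' @param path Output JSON file.
#' @return `path` invisibly; `read_geometry()` returns the `acq_geometry`.
#' @export
write_geometry <- function(g, path) {
  stopifnot(inherits(g, "acq_geometry"))
  obj <- list(name = g$name, motion = g$motion,
              sources = unname(as.data.frame(g$sources)),
              exposure_scale = g$exposure_scale,
              sid_mm = g$sid_mm, radius_mm = g$radius_mm,
              detector = unclass(g$detector))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- do.call(detector_spec, obj$detector)
  new_geometry(obj$name, as.matrix(obj$sources), obj$motion, det,
               exposure_scale = obj$exposure_scale,
               sid_mm = if (is.null(obj$sid_mm)) NA_real_ else obj$sid_mm,
               radius_mm = if (is.null(obj$radius_mm)) NA_real_ else obj$radius_mm)
}
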