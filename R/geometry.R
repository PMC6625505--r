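#' Screen geometry for pixel / visual-degree conversion
#'
#' Bundles the physical monitor parameters that own the mapping between
#' screen pixels and spherical visual degrees: the pixel pitch \code{m}
#' (mm per pixel), the viewing distance \code{d} (mm), and the physical and
#' effective display extents in pixels. Pixel coordinates are taken relative
#' to the screen center, +x right and +y up; the screen center maps to
#' azimuth 0, elevation 0.
#'
#' Defaults correspond to a 24" 1920x1080 monitor (531 mm wide, pixel pitch
#' 0.2767 mm/px) viewed at 600 mm, with an effective display area of
#' 1698 x 758 px left free of fiducial markers.
#'
#' @param m mm per pixel (> 0).
#' @param d viewing distance in mm (> 0).
#' @param width_px,height_px physical display extent in pixels.
#' @param effective_width_px,effective_height_px usable display extent in
#'   pixels (must not exceed the physical extent).
#' @param angle_formula how pixel offsets map to degrees. \code{"as_printed"}
#'   uses 2*atan2(p*m, d); \code{"half_offset"} uses the conventional
#'   visual-angle form 2*atan2(p*m, 2*d). The choice is carried in the object
#'   and echoed into downstream metadata.
#' @return An object of class \code{screen_geometry}.
#' @export
screen_geometry <- function(m = 0.2767, d = 600,
                            width_px = 1920, height_px = 1080,
                            effective_width_px = 1698,
                            effective_height_px = 758,
                            angle_formula = c("as_printed", "half_offset")) {
  angle_formula <- match.arg(angle_formula)
  stopifnot(m > 0, d > 0, width_px > 0, height_px > 0)
  if (effective_width_px > width_px || effective_height_px > height_px)
    stop("effective extent exceeds physical extent")
  structure(list(m = m, d = d,
                 width_px = width_px, height_px = height_px,
                 effective_width_px = effective_width_px,
                 effective_height_px = effective_height_px,
                 angle_formula = angle_formula),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat("Screen geometry\n")
  cat(sprintf("  pixel pitch m: %.4f mm/px, viewing distance d: %.0f mm\n",
              x$m, x$d))
  cat(sprintf("  extent: %d x %d px (effective %d x %d px)\n",
              x$width_px, x$height_px,
              x$effective_width_px, x$effective_height_px))
  cat(sprintf("  angle formula: %s\n", x$angle_formula))
  invisible(x)
}

#' Convert pixel offsets from screen center to visual degrees
#'
#' Per-axis spherical conversion beta = 2 * atan2(p * m, d) (default), where
#' p is the pixel offset from the screen center along one axis. The
#' \code{half_offset} variant divides the opposite side by 2*d, the
#' conventional visual-angle form; the two differ by a factor approaching 2
#' for small offsets.
#'
#' @param p numeric vector of pixel offsets from the screen center.
#' @param geom a \code{\link{screen_geometry}}.
#' @param angle_formula override of the formula choice stored in \code{geom}.
#' @return degrees, same length as \code{p}; an odd function of \code{p}.
#' @export
px_to_deg <- function(p, geom, angle_formula = geom$angle_formula) {
  angle_formula <- match.arg(angle_formula, c("as_printed", "half_offset"))
  denom <- if (angle_formula == "as_printed") geom$d else 2 * geom$d
  2 * atan2(p * geom$m, denom) * 180 / pi
}

#' Convert visual degrees to pixel offsets from screen center
#'
#' Exact inverse of \code{\link{px_to_deg}} under the same formula choice.
#'
#' @inheritParams px_to_deg
#' @param deg numeric vector of degrees.
#' @return pixel offsets from the screen center.
#' @export
deg_to_px <- function(deg, geom, angle_formula = geom$angle_formula) {
  angle_formula <- match.arg(angle_formula, c("as_printed", "half_offset"))
  denom <- if (angle_formula == "as_printed") geom$d else 2 * geom$d
  denom * tan(deg * pi / 360) / geom$m
}

## Cartesian unit vector for a gaze direction given as (azimuth, elevation)
## degrees in the screen-centered spherical frame. The frame is rotated so the
## screen center sits at polar 90 deg, azimuthal 90 deg; both axes then move
## the direction along great circles and contribute equivalently to angular
## distance.
.gaze_unit_vector <- function(azimuth_deg, elevation_deg) {
  polar <- (90 - elevation_deg) * pi / 180
  az <- (90 - azimuth_deg) * pi / 180
  cbind(sin(polar) * cos(az), sin(polar) * sin(az), cos(polar))
}

#' Angular (great-circle) distance between gaze directions
#'
#' Both directions are converted from screen-centered spherical coordinates
#' (azimuth = horizontal, elevation = vertical, degrees) to Cartesian unit
#' vectors in a frame rotated so the screen center lies at <90 deg, 90 deg>;
#' the cosine distance acos(f . t / (|f| |t|)) is returned in degrees.
#' Symmetric in its arguments, in [0, 180].
#'
#' @param az1,el1 azimuth/elevation of the first direction(s), degrees.
#' @param az2,el2 azimuth/elevation of the second direction(s), degrees.
#' @return angular distance(s) in degrees.
#' @export
angular_distance <- function(az1, el1, az2, el2) {
  if (any(!is.finite(c(az1, el1, az2, el2))))
    stop("non-finite gaze direction")
  m <- max(length(az1), length(el1), length(az2), length(el2))
  f <- .gaze_unit_vector(rep_len(az1, m), rep_len(el1, m))
  t <- .gaze_unit_vector(rep_len(az2, m), rep_len(el2, m))
  d <- rowSums(f * t)
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Rotate gaze coordinates into a target-aligned frame
#'
#' Planar rotation of (x, y) so that the first output axis points along a
#' target's direction of motion. With \code{direction = 90} the mapping is
#' (x, y) -> (y, -x). Norms are preserved.
#'
#' @param x,y numeric vectors, screen-frame coordinates (degrees).
#' @param direction target motion direction in degrees, 0 = +x, 90 = +y.
#' @return a list with components \code{along} (axis 1, along the target
#'   motion) and \code{ortho} (axis 2).
#' @export
rotate_to_target_direction <- function(x, y, direction) {
  direction <- direction %% 360
  th <- direction * pi / 180
  list(along = x * cos(th) + y * sin(th),
       ortho = -x * sin(th) + y * cos(th))
}
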