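# Stimulus geometry: slanted elliptical discs, two-eye pinhole projection,
# and the reprojection construction that dissociates texture-specified from
# disparity-specified slant.
#
# Coordinate convention (all lengths in cm): right-handed, origin at the
# screen centre, x rightward, y upward, z toward the viewer. The screen is
# the plane z = 0; the eyes sit at z = viewing distance, x = +/- IOD/2.
# Slant is measured in degrees from frontoparallel, as a rotation about the
# horizontal (x) axis, so a disc point with plane-frame coordinates (u, v)
# maps to (cx + u, v cos s, z0 + v sin s).

#' Viewing geometry for a two-eye display
#'
#' @param distance_cm Viewing distance from the eyes to the screen plane (cm).
#' @param iod_cm Interocular distance (cm); projections are computed for this
#'   specific eye separation.
#' @param display_width_deg Total horizontal extent of the stimulus pair in
#'   degrees of visual angle.
#' @return An object of class `viewing_geometry`.
#' @export
viewing_geometry <- function(distance_cm = 175, iod_cm = 6.2,
                             display_width_deg = 13) {
  check_number(distance_cm, "distance_cm", lower = 1e-6)
  check_number(iod_cm, "iod_cm", lower = 1e-6)
  check_number(display_width_deg, "display_width_deg", lower = 1e-6, upper = 90)
  structure(
    list(distance_cm = distance_cm, iod_cm = iod_cm,
         display_width_deg = display_width_deg),
    class = "viewing_geometry"
  )
}

#' Specification of one slanted disc
#'
#' A disc is an ellipse of width `width_cm` (across, the u axis of its own
#' frame) and length `width_cm * length_ratio` (along the slant axis),
#' centred at depth `depth_offset_cm` relative to the screen (positive =
#' toward the viewer). Texture-specified and disparity-specified slants may
#' differ, producing a cue-conflict stimulus.
#'
#' @param slant_texture_deg Slant signalled by the texture gradient (degrees
#'   from frontoparallel, in (-90, 90)).
#' @param slant_disparity_deg Slant signalled by binocular disparity; defaults
#'   to `slant_texture_deg` (no conflict).
#' @param width_cm Disc width (cm).
#' @param length_ratio Length/width ratio, in [1, 1.5].
#' @param depth_offset_cm Disc-centre depth relative to the screen (cm);
#'   +10 or -10 in the emulated study design.
#' @param side Which side of the display the disc occupies.
#' @return An object of class `plane_spec`.
#' @export
plane_spec <- function(slant_texture_deg,
                       slant_disparity_deg = slant_texture_deg,
                       width_cm = 16, length_ratio = 1.25,
                       depth_offset_cm = 10, side = c("left", "right")) {
  side <- match.arg(side)
  check_number(width_cm, "width_cm", lower = 1e-9)
  check_number(length_ratio, "length_ratio", lower = 1, upper = 1.5)
  check_number(depth_offset_cm, "depth_offset_cm")
  check_number(slant_texture_deg, "slant_texture_deg", lower = -90 + 1e-9,
               upper = 90 - 1e-9)
  check_number(slant_disparity_deg, "slant_disparity_deg", lower = -90 + 1e-9,
               upper = 90 - 1e-9)
  structure(
    list(width_cm = width_cm, length_ratio = length_ratio,
         slant_texture_deg = slant_texture_deg,
         slant_disparity_deg = slant_disparity_deg,
         depth_offset_cm = depth_offset_cm, side = side),
    class = "plane_spec"
  )
}

## Horizontal centre (cm) of a disc so that the two-disc pair spans the
## display width; the pair's outer edges touch the display edges.
disc_centre_x <- function(spec, geometry) {
  half_span <- geometry$distance_cm *
    tan(geometry$display_width_deg / 2 * pi / 180)
  cx <- half_span - spec$width_cm / 2
  if (spec$side == "left") -cx else cx
}

## Map plane-frame (u, v) coordinates to 3D world points for a given slant.
plane_to_world <- function(uv, slant_deg, centre_x, depth_offset_cm) {
  s <- slant_deg * pi / 180
  cbind(x = centre_x + uv[, 1],
        y = uv[, 2] * cos(s),
        z = depth_offset_cm + uv[, 2] * sin(s))
}

project_from_eye <- function(points3d, eye_x, distance_cm) {
  z <- points3d[, 3]
  if (any(z >= distance_cm - 1e-12)) {
    sf_geom_error("point at or behind an eye: projection undefined")
  }
  t <- distance_cm / (distance_cm - z)
  cbind(x = eye_x + (points3d[, 1] - eye_x) * t,
        y = points3d[, 2] * t)
}

#' Project 3D points to the two eyes' screen images
#'
#' Pinhole projection onto the screen plane (z = 0) from two eyes placed
#' symmetrically at x = +/- IOD/2, z = viewing distance. Points on the screen
#' plane project to identical left- and right-eye coordinates.
#'
#' @param points3d Numeric matrix with columns x, y, z (cm).
#' @param geometry A [viewing_geometry()].
#' @return A `stereo_projection`: list with `left`, `right`, and `cyclopean`
#'   n-by-2 screen-coordinate matrices sharing row order (topology).
#' @export
project_stereo <- function(points3d, geometry) {
  points3d <- as.matrix(points3d)
  if (ncol(points3d) != 3) sf_spec_error("`points3d` must have 3 columns")
  half <- geometry$iod_cm / 2
  structure(
    list(left = project_from_eye(points3d, -half, geometry$distance_cm),
         right = project_from_eye(points3d, half, geometry$distance_cm),
         cyclopean = project_from_eye(points3d, 0, geometry$distance_cm)),
    class = "stereo_projection"
  )
}

## Back-project screen points along cyclopean rays onto the plane with the
## given slant through (*, 0, depth_offset). The plane is unbounded in x, so
## the result does not depend on the disc's horizontal centre.
back_project_cyclopean <- function(screen_xy, slant_deg, depth_offset_cm,
                                   geometry) {
  s <- slant_deg * pi / 180
  d <- geometry$distance_cm
  denom <- sin(s) * screen_xy[, 2] + cos(s) * d
  if (any(abs(denom) < 1e-9)) {
    sf_geom_error("cyclopean ray parallel to the disparity-specified plane")
  }
  t <- cos(s) * (d - depth_offset_cm) / denom
  cbind(x = screen_xy[, 1] * t,
        y = screen_xy[, 2] * t,
        z = d * (1 - t))
}

#' Two-eye projection of a (possibly cue-conflict) disc stimulus
#'
#' Constructs the stereo images of a textured or dotted disc whose
#' texture-specified and disparity-specified slants may differ. The cyclopean
#' image is the projection of the pattern laid on the plane at the texture
#' slant (for dot patterns, the screen-frame dots themselves, which carry no
#' slant gradient); each image point is then assigned the depth of the plane
#' at the disparity slant along its cyclopean ray, and the two-eye projection
#' is computed from those 3D positions. The texture gradient therefore
#' signals `slant_texture_deg` while disparities signal `slant_disparity_deg`;
#' when the two slants are equal the construction reduces exactly to
#' [project_stereo()] of the single physical plane.
#'
#' @param spec A [plane_spec()].
#' @param pattern A `texture_pattern` (from [make_texture_tiles()]) or a
#'   `dot_pattern` (from [make_dot_pattern()]).
#' @param geometry A [viewing_geometry()].
#' @return A `conflict_projection`: list with `left`, `right`, `cyclopean`
#'   screen-coordinate matrices, `points3d` (the disparity-consistent 3D
#'   positions), `element` (polygon/dot index of each row, identical in both
#'   eyes), and `kind` ("tiles" or "dots").
#' @export
project_conflict_stimulus <- function(spec, pattern, geometry) {
  cx <- disc_centre_x(spec, geometry)
  if (inherits(pattern, "texture_pattern")) {
    uv <- do.call(rbind, pattern$tiles)
    element <- rep(seq_along(pattern$tiles),
                   vapply(pattern$tiles, nrow, integer(1)))
    world_tex <- plane_to_world(uv, spec$slant_texture_deg, cx,
                                spec$depth_offset_cm)
    cyc <- project_from_eye(world_tex, 0, geometry$distance_cm)
    kind <- "tiles"
  } else if (inherits(pattern, "dot_pattern")) {
    # dots are defined in the screen frame (uniform projected density)
    cyc <- pattern$dots
    element <- seq_len(nrow(cyc))
    kind <- "dots"
  } else {
    sf_spec_error("`pattern` must be a texture_pattern or dot_pattern")
  }
  p3d <- back_project_cyclopean(cyc, spec$slant_disparity_deg,
                                spec$depth_offset_cm, geometry)
  proj <- project_stereo(p3d, geometry)
  structure(
    list(left = proj$left, right = proj$right, cyclopean = proj$cyclopean,
         points3d = p3d, element = element, kind = kind, spec = spec),
    class = "conflict_projection"
  )
}
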