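# Surface patterns: Voronoi texture tiles in the plane frame and
# uniform-screen-density dot arrays.

## Closed convex clip of polygon `poly` (n x 2, open ring) against the
## half-plane { p : (p - o) . n <= 0 } (Sutherland-Hodgman, one edge).
clip_halfplane <- function(poly, o, n) {
  if (is.null(poly) || nrow(poly) < 3) return(NULL)
  s <- (poly[, 1] - o[1]) * n[1] + (poly[, 2] - o[2]) * n[2]
  inside <- s <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(NULL)
  m <- nrow(poly)
  nxt <- c(2:m, 1L)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    j <- nxt[i]
    a <- poly[i, ]; b <- poly[j, ]
    pieces <- NULL
    if (inside[i]) pieces <- rbind(pieces, a)
    if (xor(inside[i], inside[j])) {
      t <- s[i] / (s[i] - s[j])
      pieces <- rbind(pieces, a + t * (b - a))
    }
    out[[i]] <- pieces
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) < 3) NULL else unname(res)
}

## Clip a convex polygon to a convex window (both open rings): successive
## half-plane clips along the window's edges (window must be CCW).
clip_to_convex <- function(poly, window) {
  m <- nrow(window)
  nxt <- c(2:m, 1L)
  for (i in seq_len(m)) {
    e <- window[nxt[i], ] - window[i, ]
    normal <- c(e[2], -e[1])   # outward normal of a CCW window edge
    poly <- clip_halfplane(poly, window[i, ], normal)
    if (is.null(poly)) return(NULL)
  }
  poly
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i <- seq_len(nrow(poly)); j <- c(2:nrow(poly), 1L)
  abs(sum(x[i] * y[j] - x[j] * y[i])) / 2
}

ellipse_polygon <- function(a, b, n = 96L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]  # CCW
  cbind(a * cos(th), b * sin(th))
}

## Jittered regular grid covering [x0,x1] x [y0,y1].
jittered_grid <- function(x0, x1, y0, y1, spacing, jitter) {
  gx <- seq(ceiling(x0 / spacing) * spacing, x1, by = spacing)
  gy <- seq(ceiling(y0 / spacing) * spacing, y1, by = spacing)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  n <- nrow(g)
  g + cbind(stats::runif(n, -jitter, jitter), stats::runif(n, -jitter, jitter))
}

#' Voronoi texture tiles for a slanted disc
#'
#' Builds the tiled surface texture in the disc's own 2D frame: a Voronoi
#' tessellation around a square grid of generating points, each jittered
#' independently and uniformly per axis, with tiles clipped to the elliptical
#' disc boundary (half-open inclusion at the boundary). The tessellation
#' itself is computed with \pkg{deldir}.
#'
#' @param disc A [plane_spec()].
#' @param seed Integer seed; the same (disc, seed) yields identical tiles.
#' @param grid_cm Generator grid spacing (cm).
#' @param jitter_cm Half-range of the uniform per-axis generator jitter (cm).
#' @return A `texture_pattern`: list with `tiles` (list of vertex matrices in
#'   plane-frame cm), `generators` (matrix, one row per retained tile),
#'   `grid_cm`, `jitter_cm`, and the disc semi-axes `a`, `b`.
#' @export
make_texture_tiles <- function(disc, seed = NULL, grid_cm = 1,
                               jitter_cm = 0.225) {
  if (!inherits(disc, "plane_spec")) sf_spec_error("`disc` must be a plane_spec")
  check_number(grid_cm, "grid_cm", lower = 1e-9)
  check_number(jitter_cm, "jitter_cm", lower = 0)
  a <- disc$width_cm / 2
  b <- a * disc$length_ratio
  with_seed(seed, {
    pad <- grid_cm + jitter_cm
    gen <- jittered_grid(-a - pad, a + pad, -b - pad, b + pad,
                         grid_cm, jitter_cm)
    rw <- c(min(gen[, 1]), max(gen[, 1]), min(gen[, 2]), max(gen[, 2])) +
      c(-1, 1, -1, 1) * grid_cm
    dd <- deldir::deldir(gen[, 1], gen[, 2], rw = rw, suppressMsge = TRUE)
    tl <- deldir::tile.list(dd)
    window <- ellipse_polygon(a, b)
    tiles <- vector("list", length(tl))
    keep <- logical(length(tl))
    for (i in seq_along(tl)) {
      poly <- cbind(tl[[i]]$x, tl[[i]]$y)
      clipped <- clip_to_convex(poly, window)
      if (!is.null(clipped) && polygon_area(clipped) > 1e-9) {
        tiles[[i]] <- clipped
        keep[i] <- TRUE
      }
    }
    structure(
      list(tiles = tiles[keep],
           generators = gen[keep, , drop = FALSE],
           grid_cm = grid_cm, jitter_cm = jitter_cm, a = a, b = b),
      class = "texture_pattern"
    )
  })
}

## Vectorised point-in-convex-polygon (CCW open ring), boundary counts as in.
in_convex_polygon <- function(pts, poly) {
  m <- nrow(poly)
  nxt <- c(2:m, 1L)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(m)) {
    ex <- poly[nxt[i], 1] - poly[i, 1]
    ey <- poly[nxt[i], 2] - poly[i, 2]
    cross <- ex * (pts[, 2] - poly[i, 2]) - ey * (pts[, 1] - poly[i, 1])
    inside <- inside & cross >= -1e-12
  }
  inside
}

#' Uniform-density dot pattern for a disparity-only disc
#'
#' Dots are generated directly in the screen/image frame as a jittered square
#' grid restricted to the projected (cyclopean) outline of the disc at its
#' disparity-specified slant, so the projected dot density carries no slant
#' information; depths are assigned later by back-projection in
#' [project_conflict_stimulus()].
#'
#' @inheritParams make_texture_tiles
#' @param geometry A [viewing_geometry()].
#' @param jitter_cm Half-range of the uniform per-axis dot jitter (cm).
#' @return A `dot_pattern`: list with `dots` (screen-frame matrix, cm),
#'   `outline` (projected disc boundary polygon), `grid_cm`, `jitter_cm`.
#' @export
make_dot_pattern <- function(disc, geometry, seed = NULL, grid_cm = 1,
                             jitter_cm = 1.5) {
  if (!inherits(disc, "plane_spec")) sf_spec_error("`disc` must be a plane_spec")
  check_number(grid_cm, "grid_cm", lower = 1e-9)
  check_number(jitter_cm, "jitter_cm", lower = 0)
  a <- disc$width_cm / 2
  b <- a * disc$length_ratio
  cx <- disc_centre_x(disc, geometry)
  boundary_uv <- ellipse_polygon(a, b, n = 180L)
  world <- plane_to_world(boundary_uv, disc$slant_disparity_deg, cx,
                          disc$depth_offset_cm)
  outline <- project_from_eye(world, 0, geometry$distance_cm)
  if (polygon_area_signed(outline) < 0) outline <- outline[rev(seq_len(nrow(outline))), ]
  with_seed(seed, {
    pad <- jitter_cm
    dots <- jittered_grid(min(outline[, 1]) - pad, max(outline[, 1]) + pad,
                          min(outline[, 2]) - pad, max(outline[, 2]) + pad,
                          grid_cm, jitter_cm)
    dots <- dots[in_convex_polygon(dots, outline), , drop = FALSE]
    colnames(dots) <- c("x", "y")
    structure(
      list(dots = dots, outline = outline, grid_cm = grid_cm,
           jitter_cm = jitter_cm),
      class = "dot_pattern"
    )
  })
}

polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i <- seq_len(nrow(poly)); j <- c(2:nrow(poly), 1L)
  sum(x[i] * y[j] - x[j] * y[i]) / 2
}
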