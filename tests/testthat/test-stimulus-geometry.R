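# Stimulus construction: Voronoi texture tiles, uniform-screen-density dots,
# stereo projection and the cue-conflict reprojection.

geom <- viewing_geometry()

test_that("zero-jitter Voronoi tiling reduces to the unit grid", {
  disc <- plane_spec(45, length_ratio = 1)
  tp <- make_texture_tiles(disc, seed = 1, jitter_cm = 0)
  # interior tiles (generator well inside the ellipse) are exact 1 cm2 squares
  r <- sqrt(rowSums(tp$generators^2))
  interior <- which(r < tp$a - 1.5)
  expect_gt(length(interior), 50)
  areas <- vapply(tp$tiles[interior], slantfuse:::polygon_area, numeric(1))
  expect_equal(areas, rep(1, length(interior)), tolerance = 1e-9)
  nv <- vapply(tp$tiles[interior], nrow, integer(1))
  expect_true(all(nv == 4))
})

test_that("tiles partition the disc and generator count matches enumeration", {
  disc <- plane_spec(30, length_ratio = 1.25)
  tp <- make_texture_tiles(disc, seed = 3)
  a <- disc$width_cm / 2; b <- a * disc$length_ratio
  # union covers the ellipse: total tile area equals the area of the
  # polygonal window used for clipping (96-gon inscribed in the ellipse)
  win_area <- slantfuse:::polygon_area(slantfuse:::ellipse_polygon(a, b))
  expect_equal(sum(vapply(tp$tiles, slantfuse:::polygon_area, numeric(1))),
               win_area, tolerance = 1e-6)
  # interior generator count ~ ellipse area / grid cell, checked against a
  # brute-force point-in-ellipse enumeration of the jittered grid nodes
  inside <- sum((tp$generators[, 1] / a)^2 + (tp$generators[, 2] / b)^2 <= 1)
  expect_equal(inside / (pi * a * b), 1, tolerance = 0.05)
  # tiles with generators inside the ellipse are all retained
  expect_gte(length(tp$tiles), inside)
})

test_that("tile cells contain the points nearest their generator", {
  # membership oracle: random interior points must fall in the cell of their
  # nearest generator
  disc <- plane_spec(20)
  tp <- make_texture_tiles(disc, seed = 11)
  set.seed(99)
  pts <- cbind(runif(200, -5, 5), runif(200, -5, 5))
  for (k in sample(nrow(pts), 50)) {
    p <- pts[k, ]
    d2 <- (tp$generators[, 1] - p[1])^2 + (tp$generators[, 2] - p[2])^2
    i <- which.min(d2)
    expect_true(slantfuse:::in_convex_polygon(rbind(p), tp$tiles[[i]]))
  }
})

test_that("texture and dot patterns are deterministic in (spec, seed)", {
  disc <- plane_spec(52, slant_disparity_deg = 38)
  t1 <- make_texture_tiles(disc, seed = 21)
  t2 <- make_texture_tiles(disc, seed = 21)
  expect_identical(t1, t2)
  d1 <- make_dot_pattern(disc, geom, seed = 21)
  d2 <- make_dot_pattern(disc, geom, seed = 21)
  expect_identical(d1, d2)
  expect_false(identical(t1, make_texture_tiles(disc, seed = 22)))
})

test_that("zero-jitter dots form the exact grid inside the projected outline", {
  disc <- plane_spec(45)
  dp <- make_dot_pattern(disc, geom, seed = 5, jitter_cm = 0)
  off <- dp$dots - round(dp$dots)
  expect_lt(max(abs(off)), 1e-9)
  expect_true(all(slantfuse:::in_convex_polygon(dp$dots, dp$outline)))
})

test_that("dot density is uniform on the screen (chi-square over seeds)", {
  disc <- plane_spec(45)
  # pool counts in equal-area 2x2 cm bins fully inside the outline
  dp0 <- make_dot_pattern(disc, geom, seed = 1)
  out <- dp0$outline
  bx <- seq(-6, 6, by = 2) + mean(range(out[, 1]))
  by <- seq(-4, 4, by = 2)
  centres <- expand.grid(x = bx[-length(bx)] + 1, y = by[-length(by)] + 1)
  counts <- rep(0, nrow(centres))
  for (s in 1:100) {
    dp <- make_dot_pattern(disc, geom, seed = s)
    for (i in seq_len(nrow(centres))) {
      counts[i] <- counts[i] + sum(
        abs(dp$dots[, 1] - centres$x[i]) <= 1 &
          abs(dp$dots[, 2] - centres$y[i]) <= 1)
    }
  }
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("stereo projection matches the two-ray screen-plane oracle", {
  set.seed(7)
  for (k in 1:20) {
    p <- c(runif(1, -15, 15), runif(1, -10, 10), runif(1, -20, 20))
    pr <- project_stereo(rbind(p), geom)
    expect_equal(as.numeric(pr$left),
                 oracle_project(p, c(-geom$iod_cm / 2, 0, geom$distance_cm)),
                 tolerance = 1e-9)
    expect_equal(as.numeric(pr$right),
                 oracle_project(p, c(geom$iod_cm / 2, 0, geom$distance_cm)),
                 tolerance = 1e-9)
  }
  # screen-plane points have zero disparity
  pr0 <- project_stereo(cbind(3, -2, 0), geom)
  expect_equal(pr0$left, pr0$right, tolerance = 1e-12)
  # flipping depth sign flips the sign of horizontal disparity
  prp <- project_stereo(cbind(0, 0, 8), geom)
  prm <- project_stereo(cbind(0, 0, -8), geom)
  disp_p <- prp$left[1] - prp$right[1]
  disp_m <- prm$left[1] - prm$right[1]
  expect_gt(disp_p * disp_m, -Inf)
  expect_equal(sign(disp_p), -sign(disp_m))
  # point behind an eye errors
  expect_error(project_stereo(cbind(0, 0, 200), geom),
               class = "slantfuse_geom_error")
})

test_that("zero-conflict stimuli equal direct projection of one plane", {
  for (seed in c(2, 9)) {
    for (slant in c(32.5, 45, 57.5)) {
      disc <- plane_spec(slant)
      tp <- make_texture_tiles(disc, seed = seed)
      pr <- project_conflict_stimulus(disc, tp, geom)
      uv <- do.call(rbind, tp$tiles)
      w <- slantfuse:::plane_to_world(
        uv, slant, slantfuse:::disc_centre_x(disc, geom),
        disc$depth_offset_cm)
      direct <- project_stereo(w, geom)
      expect_lt(max(abs(pr$left - direct$left)), 1e-9)
      expect_lt(max(abs(pr$right - direct$right)), 1e-9)
    }
  }
})

test_that("cyclopean image of a conflict stimulus ignores disparity slant", {
  base <- plane_spec(45, slant_disparity_deg = 45)
  conf <- plane_spec(45, slant_disparity_deg = 20)
  tp <- make_texture_tiles(base, seed = 4)
  pr1 <- project_conflict_stimulus(base, tp, geom)
  pr2 <- project_conflict_stimulus(conf, tp, geom)
  expect_equal(pr1$cyclopean, pr2$cyclopean, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pr1$left, pr2$left)))
})

test_that("triangulated conflict-stimulus depths lie on the disparity plane", {
  disc <- plane_spec(57.5, slant_disparity_deg = 32.5)
  tp <- make_texture_tiles(disc, seed = 8)
  pr <- project_conflict_stimulus(disc, tp, geom)
  s <- disc$slant_disparity_deg * pi / 180
  idx <- seq(1, nrow(pr$left), length.out = 40)
  for (i in round(idx)) {
    p3 <- oracle_triangulate(pr$left[i, ], pr$right[i, ],
                             geom$iod_cm, geom$distance_cm)
    resid <- -sin(s) * p3[2] + cos(s) * (p3[3] - disc$depth_offset_cm)
    expect_lt(abs(resid), 1e-6)
  }
})

test_that("texture foreshortening at the disc centre follows the cosine law", {
  for (slant in c(20, 45, 70)) {
    disc <- plane_spec(slant)
    eps <- 1e-3
    uv <- rbind(c(0, -eps), c(0, eps))
    w <- slantfuse:::plane_to_world(uv, slant, 0, disc$depth_offset_cm)
    # package path (cyclopean projection)
    proj <- project_stereo(w, geom)$cyclopean
    ratio <- unname((proj[2, 2] - proj[1, 2]) / (2 * eps))
    # independent oracle projection of the same probe
    o1 <- oracle_project(w[1, ], c(0, 0, geom$distance_cm))
    o2 <- oracle_project(w[2, ], c(0, 0, geom$distance_cm))
    oracle_ratio <- unname((o2[2] - o1[2]) / (2 * eps))
    expect_equal(ratio, oracle_ratio, tolerance = 1e-9)
    # and equals cos(slant) x perspective magnification in the small-probe limit
    mag <- geom$distance_cm / (geom$distance_cm - disc$depth_offset_cm)
    expect_equal(ratio, cos(slant * pi / 180) * mag, tolerance = 1e-3)
  }
})

test_that("degenerate disc specifications are rejected", {
  expect_error(plane_spec(45, width_cm = 0), class = "slantfuse_spec_error")
  expect_error(plane_spec(95), class = "slantfuse_spec_error")
  expect_error(plane_spec(45, length_ratio = 2), class = "slantfuse_spec_error")
})
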