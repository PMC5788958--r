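test_that("an open scene renders sky above the horizon and ground below", {
  sc <- open_scene(sky = 255, ground = 40)
  p <- render_panorama(sc, viewpoint(0, 0, 1), noise = FALSE)
  el <- 66 - (seq_len(117) - 1)
  expect_true(all(p$grid[el > 0, ] == 255))
  expect_true(all(p$grid[el < 0, ] == 40))
})

test_that("a distant trunk renders as a dark column of the predicted width", {
  r <- 0.5; d <- 5
  sc <- one_trunk_scene(distance = d, bearing = 90, radius = r)
  p <- render_panorama(sc, viewpoint(0, 0, 1), noise = FALSE)
  half_width <- asin(r / d) * 180 / pi # 5.74 deg
  horizon_row <- which(66 - (seq_len(117) - 1) == 5) # elevation +5 deg
  dark <- which(p$grid[horizon_row, ] == 60)
  az <- (dark - 0.5) # column centres in degrees
  expect_true(all(abs(az - 90) <= half_width + 0.5))
  expect_gte(length(dark), floor(2 * half_width) - 1)

  # column membership matches a per-ray brute-force intersection oracle
  tr <- sc$trees
  for (col in 75:105) {
    expected <- ray_hits_cylinder(0, 0, 1, col - 0.5, 5, tr$x, tr$y, r,
                                  tr$height)
    expect_identical(unname(p$grid[horizon_row, col] == 60), expected)
  }
})

test_that("the viewer's own trunk self-occludes the view toward the nest", {
  sc <- two_tree_scene()
  # standing on the far side of the nest tree, looking toward azimuth 0:
  # the trunk blocks the low-elevation view in the nest direction
  vp <- trunk_viewpoint(sc, "nest", 180, 1, offset = 0.02)
  p <- render_panorama(sc, vp, noise = FALSE)
  horizon_row <- which(66 - (seq_len(117) - 1) == 0)
  expect_equal(unname(p$grid[horizon_row, 1]), 60)
  # verified against the oracle: the ray toward azimuth 0.5 deg hits the trunk
  nt <- sc$trees[sc$trees$id == "nest", ]
  expect_true(ray_hits_cylinder(vp$x, vp$y, vp$z,
                                vp$ref_bearing + 0.5, 0,
                                nt$x, nt$y, nt$radius, nt$height))
})

test_that("rotating the scene about the viewpoint shifts the panorama columns", {
  vp <- viewpoint(0.4, -0.2, 1)
  base_sc <- one_trunk_scene(distance = 4, bearing = 40, radius = 0.3)
  rotate_scene <- function(sc, k) {
    th <- -k * pi / 180 # clockwise bearing rotation in x/y coordinates
    dx <- sc$trees$x - vp$x; dy <- sc$trees$y - vp$y
    sc$trees$x <- vp$x + cos(th) * dx - sin(th) * dy
    sc$trees$y <- vp$y + sin(th) * dx + cos(th) * dy
    ndx <- sc$nest$x - vp$x; ndy <- sc$nest$y - vp$y
    sc$nest$x <- vp$x + cos(th) * ndx - sin(th) * ndy
    sc$nest$y <- vp$y + sin(th) * ndx + cos(th) * ndy
    sc
  }
  p0 <- render_panorama(base_sc, vp, noise = FALSE)
  for (k in c(0, 37, 90, 180)) {
    pk <- render_panorama(rotate_scene(base_sc, k), vp, noise = FALSE)
    expect_identical(pk$grid, rotate_panorama(p0, -k)$grid)
  }
})

test_that("raising the viewpoint lowers the apparent top of a short object", {
  sc <- one_trunk_scene(distance = 2, bearing = 90, radius = 0.3, height = 0.5)
  top_elev <- function(h) {
    p <- render_panorama(sc, viewpoint(0, 0, h), noise = FALSE)
    col <- 91 # azimuth 90.5 deg, well inside the trunk's angular width
    el <- 66 - (seq_len(117) - 1)
    max(el[p$grid[, col] == 60])
  }
  tops <- vapply(c(0, 1, 1.75), top_elev, numeric(1))
  expect_true(all(diff(tops) < 0))
})

test_that("the screen blocks all terrestrial cues below its top edge", {
  sc_full <- default_scene(screen = TRUE)
  sc_empty <- sc_full
  # keep only the nest tree (and the screen): what an enclosed viewer can see
  sc_empty$trees <- sc_empty$trees[sc_empty$trees$id == "nest", ]
  vp <- trunk_viewpoint(sc_full, "nest", 180, 1)
  p_full <- render_panorama(sc_full, vp, noise = FALSE)
  p_empty <- render_panorama(sc_empty, vp, noise = FALSE)
  # conservative bound: below the screen-top elevation via the far corner,
  # nothing outside the square can contribute a single pixel
  corner <- sqrt(2) * sc_full$screen$half_width + 0.3
  el_cut <- atan((sc_full$screen$z_max - vp$z) / corner) * 180 / pi
  el <- 66 - (seq_len(117) - 1)
  rows <- el < el_cut - 1
  expect_identical(p_full$grid[rows, ], p_empty$grid[rows, ])
})

test_that("mirroring the scene about the nest axis mirrors the panorama", {
  sc <- default_scene()
  m <- sc
  m$trees$x <- -m$trees$x
  m$nest$x <- -m$nest$x
  p <- render_panorama(sc, trunk_viewpoint(sc, "foraging", 30, 1),
                       noise = FALSE)
  pm <- render_panorama(m, trunk_viewpoint(m, "foraging", -30, 1),
                        noise = FALSE)
  expect_identical(pm$grid, p$grid[, 360:1])
})

test_that("rendering is deterministic and validates its inputs", {
  sc <- default_scene()
  vp <- trunk_viewpoint(sc, "foraging", 10, 1)
  expect_identical(render_panorama(sc, vp)$grid, render_panorama(sc, vp)$grid)
  expect_error(render_panorama(sc, vp, width = 100), "divide")
  expect_error(render_panorama(sc, vp, width = -1), "positive")
  inside <- viewpoint(sc$trees$x[1], sc$trees$y[1], 1)
  expect_error(render_panorama(sc, inside), "inside a solid")
})

test_that("panoramas survive a PNG + sidecar round trip", {
  sc <- default_scene()
  p <- render_panorama(sc, trunk_viewpoint(sc, "foraging", 0, 1))
  path <- file.path(tempdir(), "pano.png")
  write_panorama(p, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  p2 <- read_panorama(path)
  expect_equal(p2$grid, p$grid, ignore_attr = TRUE)
  expect_equal(p2$orientation, p$orientation)
})
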