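test_that("preprocessing keeps the blue channel and block-averages exactly", {
  # pure blue image: output equals the blue value everywhere
  rgb <- array(0, c(117, 360, 3))
  rgb[, , 3] <- 200
  p <- preprocess(rgb)
  expect_true(all(p$grid == 200))

  # constant 720 x 234 input downsamples to the same constant
  p2 <- preprocess(matrix(123, 234, 720))
  expect_equal(dim(p2$grid), c(117, 360))
  expect_true(all(p2$grid == 123))

  # 2x2-blocked checkerboard of {0, 200} averages to 100 everywhere,
  # verified against an independent block-mean oracle on a patch
  chk <- outer(1:234, 1:720, function(i, j) ((i + j) %% 2) * 200)
  p3 <- preprocess(chk)
  expect_true(all(p3$grid == 100))
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    oracle[i, j] <- mean(chk[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(unname(p3$grid[1:5, 1:5]), oracle)
})

test_that("preprocess rejects inputs it cannot map onto the standard grid", {
  expect_error(preprocess(matrix(0, 117, 300)), "narrower")
  expect_error(preprocess(matrix(0, 100, 540)), "whole multiples")
})

test_that("panorama rotation is an exact cyclic column shift", {
  p <- random_panorama(1)
  expect_identical(rotate_panorama(p, 0)$grid, p$grid)
  expect_identical(rotate_panorama(p, 360)$grid, p$grid)
  expect_identical(rotate_panorama(rotate_panorama(p, 90), 270)$grid, p$grid)
  # index-shift oracle, checked exhaustively
  r37 <- rotate_panorama(p, 37)
  for (cc in seq_len(360)) {
    expect_identical(r37$grid[, cc], p$grid[, ((cc - 1 + 37) %% 360) + 1])
  }
  expect_error(rotate_panorama(p, 12.5), "whole number")
})

test_that("the rotIDF matches hand-computed values on a toy grid", {
  ref <- as_panorama(matrix(c(10, 0, 0, 0, 0, 0, 0, 0), 2, 4))
  tst <- as_panorama(matrix(c(0, 0, 10, 0, 0, 0, 0, 0), 2, 4))
  curve <- rotidf(ref, tst)
  expect_equal(curve$mismatch, c(20, 0, 20, 20))
  expect_equal(curve$rotation, c(0, 90, 180, 270))
  expect_equal(curve$best_rotation, 90)
  expect_equal(curve$best_mismatch, 0)
})

test_that("self-comparison gives a zero minimum at rotation zero", {
  p <- random_panorama(2)
  curve <- rotidf(p, p)
  expect_equal(curve$mismatch[1], 0)
  expect_equal(curve$best_rotation, 0)
  expect_equal(valley_depth(curve), 1) # zero min over a positive mean
})

test_that("the rotIDF agrees exactly with a naive double-loop oracle", {
  for (seed in 1:3) {
    ref <- random_panorama(seed * 11, width = 72, height = 20)
    tst <- random_panorama(seed * 13, width = 72, height = 20)
    expect_identical(rotidf(ref, tst)$mismatch, rotidf_oracle(ref$grid, tst$grid))
    expect_equal(rotidf(ref, tst, metric = "rms")$mismatch,
                 rotidf_oracle(ref$grid, tst$grid, rms = TRUE))
  }
})

test_that("the rotIDF is shift-equivariant and symmetric under exchange", {
  ref <- random_panorama(5)
  tst <- random_panorama(6)
  base <- rotidf(ref, tst)$mismatch
  for (k in c(1, 37, 200)) {
    shifted <- rotidf(ref, rotate_panorama(tst, k))$mismatch
    expect_equal(shifted, base[((seq_len(360) - 1 + k) %% 360) + 1])
  }
  # rotidf(a, b)[r] = rotidf(b, a)[(-r) mod 360]
  rev <- rotidf(tst, ref)$mismatch
  expect_equal(base, rev[((-(seq_len(360) - 1)) %% 360) + 1])
  # SAD bounds
  expect_true(all(base >= 0 & base <= 360 * 117 * 255))
})

test_that("SAD and RMS agree on the aligning rotation of shifted copies", {
  sc <- default_scene()
  p <- render_panorama(sc, trunk_viewpoint(sc, "foraging", 0, 1))
  shifted <- rotate_panorama(p, 123)
  sad <- rotidf(p, shifted)
  rms <- rotidf(p, shifted, metric = "rms")
  expect_equal(sad$best_rotation, rms$best_rotation)
  expect_equal(sad$best_mismatch, 0)
})

test_that("argmin ties break toward the smallest wrapped rotation", {
  flat <- as_panorama(matrix(5, 10, 360))
  curve <- rotidf(flat, flat) # all rotations tie at zero
  expect_equal(curve$best_rotation, 0)
  expect_equal(valley_depth(curve), 0) # all-zero curve: depth defined as 0
  # two-way tie at +90 and -90, nothing at 0
  m <- rep(10, 360); m[91] <- 1; m[271] <- 1
  expect_equal(trunknav:::pick_best_rotation(m, 0:359), 90)
})

test_that("constant curves have zero valley depth and no clear minimum", {
  a <- as_panorama(matrix(10, 10, 360))
  b <- as_panorama(matrix(30, 10, 360))
  curve <- rotidf(a, b)
  expect_equal(valley_depth(curve), 0)
  expect_false(has_clear_minimum(curve))
})

test_that("nest-side views are more matchable than far-side views", {
  sc <- default_scene()
  base <- render_panorama(sc, trunk_viewpoint(sc, "foraging", 0, 0))
  near <- rotidf(base, render_panorama(sc, trunk_viewpoint(sc, "foraging", 0, 1)))
  far <- rotidf(base, render_panorama(sc, trunk_viewpoint(sc, "foraging", 180, 1)))
  expect_gt(valley_depth(near), valley_depth(far))
})

test_that("rotIDF tidiers and exporters expose the curve and its summary", {
  p <- random_panorama(7)
  curve <- rotidf(p, rotate_panorama(p, 40))
  td <- tidy(curve)
  expect_equal(nrow(td), 360)
  expect_named(td, c("rotation_deg", "mismatch"))
  gl <- glance(curve)
  expect_equal(gl$best_mismatch, 0)
  expect_true(gl$clear_minimum)
  csv <- file.path(tempdir(), "curve.csv")
  jsn <- file.path(tempdir(), "curve.json")
  write_rotidf(curve, csv, jsn)
  back <- utils::read.csv(csv)
  expect_equal(back$mismatch, curve$mismatch)
  expect_equal(jsonlite::read_json(jsn)$best_rotation, gl$best_rotation)
})
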