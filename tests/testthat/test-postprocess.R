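test_that("grayscale conversion uses luminance weights and drops alpha", {
  white <- array(1, dim = c(1, 1, 3))
  expect_equal(to_grayscale(white)[1, 1], 1.0)
  green <- array(c(0, 1, 0), dim = c(1, 1, 3))
  expect_equal(to_grayscale(green)[1, 1], 0.7154)
  rgba <- array(runif(2 * 2 * 4), dim = c(2, 2, 4))
  expect_equal(to_grayscale(rgba), to_grayscale(rgba[, , 1:3]))
  gray <- matrix(0.4, 3, 3)
  expect_identical(to_grayscale(gray), gray)
  expect_error(to_grayscale(array(0, dim = c(2, 2, 2))), "channel")
})

test_that("thresholding is inclusive at the cut value", {
  g <- matrix(c(0.35, 0.350001, 0, 1), 2, 2)
  m <- threshold_heatmap(g, postprocess_config())
  expect_identical(m, matrix(c(0L, 1L, 0L, 1L), 2, 2))
  expect_true(all(threshold_heatmap(matrix(0, 4, 4)) == 0))
})

test_that("component labelling respects 4- and 8-connectivity", {
  m <- matrix(0L, 5, 5)
  m[1, 1] <- 1L; m[2, 2] <- 1L  # diagonal touch
  expect_identical(max(label_components(m, 4L)), 2L)
  expect_identical(max(label_components(m, 8L)), 1L)
  m2 <- matrix(0L, 4, 4); m2[1, ] <- 1L; m2[3, ] <- 1L
  expect_identical(max(label_components(m2, 4L)), 2L)
  expect_identical(max(label_components(matrix(0L, 3, 3))), 0L)
})

test_that("small clusters are removed and surviving clusters dilated", {
  cfg <- postprocess_config()
  # 9-pixel component: below the size cut, removed
  m9 <- matrix(0L, 20, 20); m9[5:7, 5:7] <- 1L
  expect_true(all(process_clusters(m9, cfg) == 0))
  # 12-pixel rectangle: kept and expanded by a one-pixel ring, equal to a
  # brute-force 3x3 dilation of the rectangle
  m12 <- matrix(0L, 20, 20); m12[5:7, 5:8] <- 1L
  out <- process_clusters(m12, cfg)
  expect_identical(out + 0L, brute_dilate(m12, 3L))
  # output contains each surviving component and stays within its dilation
  expect_true(all(out[m12 == 1L] == 1L))
  expect_true(all(out <= brute_dilate(m12, 3L)))
  # empty input passes through
  expect_true(all(process_clusters(matrix(0L, 8, 8), cfg) == 0))
  # mixed case: only the large component survives
  mix <- matrix(0L, 30, 30); mix[2:3, 2:4] <- 1L; mix[10:14, 10:14] <- 1L
  out2 <- process_clusters(mix, cfg)
  expect_true(all(out2[2:3, 2:4] == 0L))
  expect_true(all(out2[10:14, 10:14] == 1L))
})

test_that("hole filling matches an independent flood-fill oracle and is idempotent", {
  ring <- matrix(0L, 9, 9); ring[2:8, 2:8] <- 1L; ring[3:7, 3:7] <- 0L
  filled <- fill_holes(ring)
  expect_identical(filled + 0L, brute_fill_holes(ring))
  expect_true(all(filled[2:8, 2:8] == 1L))
  expect_identical(fill_holes(filled), filled)
  expect_true(all(fill_holes(matrix(0L, 5, 5)) == 0))
  # background touching the border is never filled
  open_c <- ring; open_c[5, 2] <- 0L  # breach the ring
  expect_identical(fill_holes(open_c) + 0L, brute_fill_holes(open_c))
})

test_that("closing uses the inscribed-ellipse kernel and is idempotent on its output", {
  k5 <- xaiseg:::ellipse_kernel(5L)
  expect_identical(k5, matrix(as.integer(c(0, 1, 1, 1, 0,
                                           0, 1, 1, 1, 0,
                                           1, 1, 1, 1, 1,
                                           0, 1, 1, 1, 0,
                                           0, 1, 1, 1, 0)), 5, 5))
  cfg <- postprocess_config()
  blob <- matrix(0L, 21, 21); blob[6:16, 6:16] <- 1L
  closed <- fill_and_close(blob, cfg)
  # solid convex blob: closing leaves it unchanged (dilate-then-erode oracle)
  kern <- xaiseg:::ellipse_kernel(5L)
  oracle <- xaiseg:::binary_erode(xaiseg:::binary_dilate(blob, kern), kern)
  expect_identical(closed, oracle)
  expect_identical(closed + 0L, blob + 0L)
  expect_identical(fill_and_close(closed, cfg), closed)
  expect_true(all(fill_and_close(matrix(0L, 6, 6), cfg) == 0))
})

test_that("convex hull mask honours the few-point guard and fills corner sets", {
  m2 <- matrix(0L, 5, 5); m2[1, 1] <- 1L; m2[5, 5] <- 1L
  expect_true(all(convex_hull_mask(m2) == 0))
  # collinear points degenerate to an empty mask
  mc <- matrix(0L, 5, 5); mc[2, 1:4] <- 1L
  expect_true(all(convex_hull_mask(mc) == 0))
  # 4 corners of a 5x5 square fill the whole 25-pixel block
  m4 <- matrix(0L, 7, 7); m4[2, 2] <- 1L; m4[2, 6] <- 1L; m4[6, 2] <- 1L
  m4[6, 6] <- 1L
  hull <- convex_hull_mask(m4)
  # point-in-polygon oracle: exactly the pixels of the square block
  oracle <- matrix(0L, 7, 7); oracle[2:6, 2:6] <- 1L
  expect_identical(hull + 0L, oracle + 0L)
  # already convex and filled: output contains input with bounded growth
  solid <- matrix(0L, 15, 15); solid[4:11, 5:12] <- 1L
  h2 <- convex_hull_mask(solid)
  expect_true(all(h2[solid == 1L] == 1L))
  expect_lte(sum(h2), sum(solid) * 1.05)
})

test_that("process_mask composes the faithful pipeline", {
  cfg <- postprocess_config()
  # two well-separated suprathreshold blobs: faithful mask is one convex
  # region spanning both (hull of the union)
  hm <- matrix(0, 40, 40)
  hm[5:10, 5:10] <- 0.9; hm[28:34, 28:34] <- 0.8
  mask <- process_mask(hm, cfg)
  supra <- threshold_heatmap(hm, cfg)
  expect_true(all(mask[supra == 1L] == 1L))           # hull contains both blobs
  expect_true(mask[20, 20] == 1L)                     # and the gap between them
  hull_oracle <- convex_hull_mask(supra)
  expect_identical(mask, hull_oracle)
  # <= 2 suprathreshold pixels: guard returns an empty mask
  tiny <- matrix(0, 10, 10); tiny[3, 3] <- 0.9; tiny[7, 7] <- 0.9
  expect_true(all(process_mask(tiny, cfg) == 0))
  # all-suprathreshold heatmap: hull covers the whole frame
  full <- matrix(0.9, 12, 12)
  expect_true(all(process_mask(full, cfg) == 1L))
})

test_that("cleaned mode hulls the closed mask and differs on noisy heatmaps", {
  hm <- matrix(0, 40, 40)
  hm[10:20, 10:20] <- 0.9      # real blob
  hm[35, 35] <- 0.9            # isolated speck (below min_cluster_size)
  faithful <- process_mask(hm, postprocess_config(mode = "faithful"))
  cleaned <- process_mask(hm, postprocess_config(mode = "cleaned"))
  expect_false(identical(faithful, cleaned))
  # the speck drags the faithful hull toward the corner; cleaned ignores it
  expect_identical(faithful[35, 35], 1L)
  expect_identical(cleaned[35, 35], 0L)
  expect_true(all(cleaned[11:19, 11:19] == 1L))
})

test_that("process_mask reads heatmap PNGs from disk", {
  hm <- matrix(0, 20, 20); hm[5:12, 5:12] <- 0.8
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(hm, path)
  expect_identical(process_mask(path), process_mask(hm))
  expect_error(process_mask("no/such/file.png"), "cannot read")
})

test_that("raising the threshold never enlarges the suprathreshold set", {
  set.seed(5)
  hm <- matrix(runif(400), 20, 20)
  s1 <- threshold_heatmap(hm, postprocess_config(threshold = 0.3))
  s2 <- threshold_heatmap(hm, postprocess_config(threshold = 0.5))
  expect_true(all(s2 <= s1))
})

test_that("overlay blends a white mask additively with saturation", {
  cfg <- postprocess_config()
  img <- matrix(0.5, 8, 8)
  zero <- overlay_mask(img, matrix(0L, 8, 8), cfg)
  expect_true(all(zero[, , 1] == round(0.5 * 255)))
  # full mask on black: uniform gray at round(255 * 0.7)
  black <- matrix(0, 8, 8)
  full <- overlay_mask(black, matrix(1L, 8, 8), cfg)
  expect_true(all(full == round(255 * 0.7)))
  # full mask on white saturates at 255
  white <- matrix(1, 8, 8)
  expect_true(all(overlay_mask(white, matrix(1L, 8, 8), cfg) == 255))
  # half-resolution mask is upscaled before blending
  half <- matrix(0L, 4, 4); half[1:2, 1:2] <- 1L
  ov <- overlay_mask(img, half, cfg)
  expect_identical(dim(ov), c(8L, 8L, 3L))
})
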