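# Heatmap assembly, conservation, locality, and overlay rendering.

test_that("patch heatmaps localise single-pixel corruption", {
  x <- array(0.5, c(64, 64, 3))
  expect_true(all(patch_heatmap(x, x) == 0))
  y <- x; y[40, 12, ] <- 0.9
  m <- patch_heatmap(x, y, "mse")
  expect_true(all(m >= 0))
  expect_equal(which(m == max(m), arr.ind = TRUE)[1, ], c(row = 40, col = 12))
})

test_that("assembled heatmaps respect placement, validity, and conservation", {
  maps <- list(matrix(2, 64, 64), matrix(5, 64, 64))
  hm <- assemble_image_heatmap(maps, list(c(0, 0), c(130, 130)),
                               source_shape = c(300, 300))
  expect_true(all(hm$values[1:130, 1:130] == 2))
  expect_true(all(hm$values[131:260, 131:260] == 5))
  expect_true(all(hm$values[hm$valid_mask == 0] == 0))
  # conservation: window sums equal the upscaled map sums (constants exact)
  expect_equal(sum(hm$values[1:130, 1:130]), 2 * 130^2)
  # single patch: nonzero only inside its window
  h1 <- assemble_image_heatmap(list(matrix(1, 64, 64)), list(c(0, 0)),
                               c(200, 200))
  expect_equal(sum(h1$values), 130^2)
  expect_equal(sum(h1$valid_mask), 130^2)
})

test_that("assembly rejects overlaps and out-of-bounds origins", {
  maps <- list(matrix(1, 64, 64), matrix(1, 64, 64))
  expect_error(assemble_image_heatmap(maps, list(c(0, 0), c(60, 0)), c(300, 300)),
               "overlap")
  expect_error(assemble_image_heatmap(maps[1], list(c(250, 0)), c(300, 300)),
               "bounds")
})

test_that("editing one patch window only changes that window", {
  set.seed(6)
  base <- lapply(1:4, function(i) matrix(runif(64 * 64), 64, 64))
  origins <- list(c(0, 0), c(0, 130), c(130, 0), c(130, 130))
  h0 <- assemble_image_heatmap(base, origins, c(260, 260))
  edited <- base
  edited[[2]][10, 10] <- 99
  h1 <- assemble_image_heatmap(edited, origins, c(260, 260))
  diff <- h1$values != h0$values
  expect_true(any(diff[1:130, 131:260]))
  expect_false(any(diff[, 1:130]))
  expect_false(any(diff[131:260, ]))
})

test_that("nearest-neighbour upscaling preserves constant windows exactly", {
  m <- matrix(3.25, 64, 64)
  up <- resize_nearest(m, 130, 130)
  expect_true(all(up == 3.25))
  # disassemble(assemble(constant)) is exact
  hm <- assemble_image_heatmap(list(m), list(c(0, 0)), c(130, 130))
  expect_true(all(hm$values == 3.25))
})

test_that("overlays blend the colormap inside the valid mask only", {
  img <- array(0.2, c(130, 130, 3))
  hm <- assemble_image_heatmap(list(matrix(0, 64, 64)), list(c(0, 0)),
                               c(130, 130))
  ov <- render_overlay(hm, img)
  expect_equal(dim(ov), dim(img))
  expect_true(all(ov >= 0 & ov <= 1))
  # zero heatmap: uniform low-end colour inside the mask
  expect_equal(length(unique(round(as.numeric(ov[, , 3]), 6))), 1)
  # invalid pixels show the raw image
  hm2 <- assemble_image_heatmap(list(matrix(1, 64, 64)), list(c(0, 0)),
                                c(200, 200))
  ov2 <- render_overlay(hm2, array(0.2, c(200, 200, 3)))
  expect_equal(ov2[190, 190, 1], 0.2)
  # max-valued pixel maps to the top colormap colour under min-max scaling
  grad_map <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  hm3 <- assemble_image_heatmap(list(grad_map), list(c(0, 0)), c(130, 130))
  ov3 <- render_overlay(hm3, array(0, c(130, 130, 3)), alpha = 1)
  top <- berryvae:::heat_colormap()[256, ]
  idx <- which(hm3$values == max(hm3$values), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(ov3[idx[1], idx[2], ]), top, tolerance = 0.02)
})

test_that("small-blob suppression removes isolated detections", {
  v <- matrix(0, 100, 100)
  v[40:60, 40:60] <- 1      # 441-px blob
  v[5, 5] <- 1              # singleton
  hm <- structure(list(values = v, valid_mask = matrix(1, 100, 100),
                       scene_id = "s", metric = "mse"),
                  class = "image_heatmap")
  out <- suppress_small_blobs(hm, threshold = 0.5, min_pixels = 10)
  expect_equal(out$values[5, 5], 0)
  expect_equal(sum(out$values), 441)
})
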