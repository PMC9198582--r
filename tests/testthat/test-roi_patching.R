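# Patch grid extraction, labelling, resizing, and the colour segmenter.

test_that("extract_patches tiles a fully covered image on the expected grid", {
  img <- array(runif(260 * 260 * 3), c(260, 260, 3))
  roi <- matrix(1, 260, 260)
  ps <- extract_patches(img, roi, patch_size = 130, coverage_threshold = 0.5)
  origins <- t(vapply(ps$patches, function(p) p$origin, integer(2)))
  expect_equal(nrow(origins), 4)
  expect_equal(origins, rbind(c(0, 0), c(0, 130), c(130, 0), c(130, 130)))
  # row-major order and half-open windows inside bounds
  for (p in ps$patches) {
    expect_true(all(p$origin + p$source_size <= c(260, 260)))
    expect_equal(dim(p$pixels), c(64, 64, 3))
    expect_true(all(p$pixels >= 0 & p$pixels <= 1))
  }
})

test_that("extract_patches respects the ROI coverage rule", {
  img <- array(0.5, c(260, 260, 3))
  expect_length(extract_patches(img, matrix(0, 260, 260),
                                coverage_threshold = 0.1)$patches, 0)
  # exactly one quadrant covered at 60%
  roi <- matrix(0, 260, 260)
  roi[1:130, 1:78] <- 1   # 60% of the (1,1) window columns
  ps <- extract_patches(img, roi, coverage_threshold = 0.5)
  expect_length(ps$patches, 1)
  expect_equal(ps$patches[[1]]$origin, c(0L, 0L))
  # coverage monotonicity: higher threshold never keeps more patches
  roi2 <- matrix(runif(260 * 260) < 0.4, 260, 260) * 1
  n_kept <- vapply(c(0, 0.2, 0.4, 0.6, 1),
                   function(ct) length(extract_patches(img, roi2,
                     coverage_threshold = ct)$patches), numeric(1))
  expect_true(all(diff(n_kept) <= 0))
  expect_error(extract_patches(img, matrix(1, 10, 10)), "share")
  expect_error(extract_patches(array(0.5, c(100, 100, 3)),
                               matrix(1, 100, 100), patch_size = 130),
               "exceeds")
})

test_that("patch windows partition the grid area without overlap", {
  img <- array(0.5, c(300, 400, 3))
  ps <- extract_patches(img, matrix(1, 300, 400), patch_size = 100,
                        coverage_threshold = 0)
  counts <- matrix(0, 300, 400)
  for (p in ps$patches) {
    counts[(p$origin[1] + 1):(p$origin[1] + 100),
           (p$origin[2] + 1):(p$origin[2] + 100)] <-
      counts[(p$origin[1] + 1):(p$origin[1] + 100),
             (p$origin[2] + 1):(p$origin[2] + 100)] + 1
  }
  expect_true(all(counts <= 1))
  expect_equal(sum(counts), 300 * 400)  # 3x4 grid covers everything
  # deterministic: identical origins on re-run
  ps2 <- extract_patches(img, matrix(1, 300, 400), patch_size = 100,
                         coverage_threshold = 0)
  expect_identical(lapply(ps$patches, `[[`, "origin"),
                   lapply(ps2$patches, `[[`, "origin"))
})

test_that("resize_patch is mean-preserving and information-retaining", {
  # constants stay constant
  out <- resize_patch(array(0.7, c(130, 130, 3)), 64)
  expect_true(all(abs(out - 0.7) < 1e-12))
  expect_equal(attr(out, "interpolation"), "area")
  # checkerboard of period 2: area averaging preserves the mean within 1%
  cb <- matrix(rep(c(0, 1), length.out = 130 * 130), 130, 130)
  ds <- resize_patch(cb, 64)
  expect_lt(abs(mean(ds) - mean(cb)), 0.01)
  # down-up round trip stays correlated with a smooth original
  set.seed(5)
  orig <- berryvae:::blur_gaussian(matrix(runif(130 * 130), 130, 130), 4)
  down <- resize_patch(orig, 64)
  up <- berryvae:::resize_area(down, 130, 130)
  expect_gt(cor(as.numeric(orig), as.numeric(up)), 0.5)
  expect_error(resize_patch(matrix(0, 10, 20)), "square")
})

test_that("label_patch counts anomaly pixels inside the source window", {
  p <- berry_patch(array(0.5, c(64, 64, 3)), origin = c(10, 20),
                   source_size = 130, scene_id = "s")
  mask <- matrix(0, 200, 200)
  expect_equal(label_patch(p, mask), "healthy")
  mask[40:59, 40:49] <- 1   # 200 pixels inside the window
  expect_equal(label_patch(p, mask, min_anomalous_pixels = 1), "anomalous")
  mask2 <- matrix(0, 200, 200); mask2[40:49, 40] <- 1  # 10 pixels
  expect_equal(label_patch(p, mask2, min_anomalous_pixels = 20), "healthy")
  pbad <- berry_patch(array(0.5, c(64, 64, 3)), origin = c(150, 150),
                      source_size = 130, scene_id = "s")
  expect_error(label_patch(pbad, mask), "bounds")
})

test_that("colour segmenter recovers the berry mask on synthetic scenes", {
  sc <- small_scene(seed = 31)
  m <- color_threshold_segmenter(sc$image)
  expect_true(all(m %in% c(0, 1)))
  iou <- sum(m & sc$berry_mask) / sum(m | sc$berry_mask)
  expect_gt(iou, 0.7)
  # background-only image yields an empty mask
  bg <- array(rep(c(0.36, 0.30, 0.26), each = 50 * 50), c(50, 50, 3))
  expect_equal(sum(color_threshold_segmenter(bg)), 0)
})
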