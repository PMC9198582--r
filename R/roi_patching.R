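# Region-of-interest patching: tile an image on a non-overlapping 130x130
# grid anchored at (0,0), keep tiles with enough ROI coverage, and resize
# each kept tile to 64x64 by area averaging. Coordinates are 0-based,
# row-major, half-open windows throughout.

#' A single image patch
#'
#' @param pixels target_size x target_size x C array in \[0,1\].
#' @param origin integer (row, col) of the source window's top-left corner,
#'   0-based.
#' @param source_size edge of the source window in pixels.
#' @param scene_id identifier of the source image.
#' @param label `"healthy"`, `"anomalous"` or `"unlabeled"`.
#' @param stage_tag growth-stage tag (`"early"` / `"late"` / other).
#' @return object of class `berry_patch`.
#' @export
berry_patch <- function(pixels, origin, source_size = 130L,
                        scene_id = "scene", label = "unlabeled",
                        stage_tag = "unlabeled") {
  check_that(all(pixels >= 0 & pixels <= 1), "patch pixels must lie in [0,1]")
  structure(list(pixels = pixels, origin = as.integer(origin),
                 source_size = as.integer(source_size), scene_id = scene_id,
                 label = label, stage_tag = stage_tag,
                 patch_id = sprintf("%s:%d,%d", scene_id, origin[1], origin[2])),
            class = "berry_patch")
}

as_patch_list <- function(x) {
  if (inherits(x, "patch_set")) return(x$patches)
  if (inherits(x, "berry_patch")) return(list(x))
  check_that(is.list(x), "expected a patch_set or list of berry_patch")
  x
}

#' Extract the non-overlapping patch grid from an image
#'
#' Tiles the image on a regular grid anchored at pixel (0,0); right/bottom
#' residual margins narrower than `patch_size` are discarded. A tile is kept
#' iff the fraction of ROI pixels inside it is at least
#' `coverage_threshold`; kept tiles are resized to `target_size` (area
#' averaging) and returned in row-major order.
#'
#' @param image H x W x C array.
#' @param roi_mask H x W 0/1 matrix marking the region of interest (berries).
#' @param patch_size source window edge in pixels.
#' @param coverage_threshold minimum ROI fraction per kept tile, in \[0,1\].
#' @param target_size output patch edge in pixels.
#' @param scene_id,stage_tag provenance carried onto every patch.
#' @return object of class `patch_set` with fields `patches`, `source_shape`,
#'   `coverage_threshold`.
#' @export
extract_patches <- function(image, roi_mask, patch_size = 130L,
                            coverage_threshold = 0.1, target_size = 64L,
                            scene_id = "scene", stage_tag = "unlabeled") {
  H <- dim(image)[1]; W <- dim(image)[2]
  check_that(nrow(roi_mask) == H && ncol(roi_mask) == W,
             "image and roi_mask must share height/width")
  check_that(patch_size <= min(H, W),
             sprintf("patch_size (%d) exceeds image size (%dx%d)",
                     patch_size, H, W))
  n_r <- H %/% patch_size
  n_c <- W %/% patch_size
  patches <- list()
  for (r in seq_len(n_r)) {            # row-major over the grid
    for (cc in seq_len(n_c)) {
      r0 <- (r - 1L) * patch_size      # 0-based origins, half-open windows
      c0 <- (cc - 1L) * patch_size
      rows <- (r0 + 1):(r0 + patch_size)
      cols <- (c0 + 1):(c0 + patch_size)
      cov <- mean(roi_mask[rows, cols] > 0)
      if (cov >= coverage_threshold) {
        tile <- image[rows, cols, , drop = FALSE]
        px <- clamp01(resize_patch(tile, target_size))
        patches <- c(patches, list(berry_patch(
          px, c(r0, c0), patch_size, scene_id, "unlabeled", stage_tag)))
      }
    }
  }
  structure(list(patches = patches, source_shape = c(H, W),
                 coverage_threshold = coverage_threshold),
            class = "patch_set")
}

#' Resize a square patch
#'
#' Area-averaging (box filter) resampling, the mean-preserving anti-aliased
#' choice for downsampling. The interpolation method is recorded in the
#' `interpolation` attribute.
#'
#' @param pixels square H x H matrix or H x H x C array.
#' @param target target edge in pixels.
#' @return resized matrix/array with attribute `interpolation = "area"`.
#' @export
resize_patch <- function(pixels, target = 64L) {
  h <- if (is.matrix(pixels)) nrow(pixels) else dim(pixels)[1]
  w <- if (is.matrix(pixels)) ncol(pixels) else dim(pixels)[2]
  check_that(h == w, sprintf("resize_patch needs a square input, got %dx%d", h, w))
  out <- resize_area(pixels, target, target)
  attr(out, "interpolation") <- "area"
  out
}

#' Label a patch from the ground-truth anomaly mask
#'
#' A patch is anomalous iff its source window contains at least
#' `min_anomalous_pixels` anomaly pixels (at source scale).
#'
#' @param patch a `berry_patch`.
#' @param anomaly_mask H x W 0/1 matrix covering the patch's source window.
#' @param min_anomalous_pixels count threshold.
#' @return `"healthy"` or `"anomalous"`.
#' @export
label_patch <- function(patch, anomaly_mask, min_anomalous_pixels = 30L) {
  o <- patch$origin; s <- patch$source_size
  check_that(o[1] >= 0 && o[2] >= 0 &&
             o[1] + s <= nrow(anomaly_mask) && o[2] + s <= ncol(anomaly_mask),
             "patch window lies outside the anomaly mask bounds")
  n_bad <- sum(anomaly_mask[(o[1] + 1):(o[1] + s), (o[2] + 1):(o[2] + s)] > 0)
  if (n_bad >= min_anomalous_pixels) "anomalous" else "healthy"
}

#' Patch a labelled scene
#'
#' Convenience wrapper: extracts the patch grid using the scene's berry mask
#' as ROI and labels every kept patch from the scene's anomaly mask.
#'
#' @param scene a `labeled_scene`.
#' @param patch_size,coverage_threshold,target_size see [extract_patches()].
#' @param min_anomalous_pixels see [label_patch()].
#' @return a `patch_set` with labelled patches.
#' @export
scene_patches <- function(scene, patch_size = 130L, coverage_threshold = 0.1,
                          target_size = 64L, min_anomalous_pixels = 30L) {
  stopifnot(inherits(scene, "labeled_scene"))
  ps <- extract_patches(scene$image, scene$berry_mask, patch_size,
                        coverage_threshold, target_size,
                        scene_id = scene$scene_id, stage_tag = scene$stage_tag)
  ps$patches <- lapply(ps$patches, function(p) {
    p$label <- label_patch(p, scene$anomaly_mask, min_anomalous_pixels)
    p
  })
  ps
}

#' Colour-threshold berry segmenter for synthetic scenes
#'
#' A simple stand-in segmenter valid on the package's synthetic scenes (the
#' field pipeline would use a trained segmentation network instead): marks
#' pixels whose hue falls in `hue_window` and removes connected components
#' smaller than `min_component_area`.
#'
#' @param image H x W x 3 RGB array in \[0,1\].
#' @param hue_window (lo, hi) hue interval on the \[0,1\] hue circle.
#' @param min_component_area minimum component size in pixels.
#' @return H x W 0/1 mask.
#' @export
color_threshold_segmenter <- function(image, hue_window = c(0.16, 0.45),
                                      min_component_area = 50L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  hsv <- grDevices::rgb2hsv(r = as.numeric(image[, , 1]),
                            g = as.numeric(image[, , 2]),
                            b = as.numeric(image[, , 3]), maxColorValue = 1)
  keep <- hsv[1, ] >= hue_window[1] & hsv[1, ] <= hue_window[2] &
    hsv[2, ] > 0.1 & hsv[3, ] > 0.05
  mask <- matrix(as.numeric(keep), H, W)
  if (min_component_area > 1 && any(mask > 0)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_component_area)
    if (length(small)) mask[lab %in% small] <- 0
  }
  mask
}

#' Write a patch manifest (JSON lines)
#'
#' One JSON object per patch: patch_id, scene_id, origin, source_size,
#' label, stage_tag.
#'
#' @param patches a `patch_set` or list of patches.
#' @param path output file.
#' @param dump_dir optional directory to also dump each patch as PNG.
#' @return the path, invisibly.
#' @export
write_patch_manifest <- function(patches, path, dump_dir = NULL) {
  pl <- as_patch_list(patches)
  lines <- vapply(pl, function(p) jsonlite::toJSON(list(
    patch_id = p$patch_id, scene_id = p$scene_id,
    origin = p$origin, source_size = p$source_size,
    label = p$label, stage_tag = p$stage_tag), auto_unbox = TRUE),
    character(1))
  writeLines(lines, path)
  if (!is.null(dump_dir)) {
    dir.create(dump_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in pl)
      write_image_png(p$pixels, file.path(dump_dir,
        paste0(gsub("[:,]", "_", p$patch_id), ".png")))
  }
  invisible(path)
}

#' @export
print.patch_set <- function(x, ...) {
  labs <- table(vapply(x$patches, function(p) p$label, character(1)))
  cat(sprintf("<patch_set %d patches from %dx%d (%s)>\n", length(x$patches),
              x$source_shape[1], x$source_shape[2],
              paste(names(labs), labs, sep = "=", collapse = ", ")))
  invisible(x)
}
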