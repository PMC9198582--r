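# Pixel-wise anomaly heatmaps: per-patch reconstruction-error maps,
# reassembled over the source image's non-overlapping patch grid, plus a
# colour overlay renderer (red = anomalous, dark blue = not anomalous).

#' Pixel-wise loss heatmap of one patch
#'
#' Channel-averaged pixel loss map between a patch and its reconstruction
#' (squared error by default, which penalises anomalous regions hardest).
#'
#' @param x,x_hat patch and reconstruction, H x W x C arrays.
#' @param metric `"mse"`, `"l1"` or `"bce"`.
#' @return H x W non-negative matrix.
#' @export
patch_heatmap <- function(x, x_hat, metric = "mse")
  pixel_loss_map(x, x_hat, metric)$map

#' Assemble per-patch heatmaps into a full-image heatmap
#'
#' Every patch map is upscaled back to its source window (nearest neighbour,
#' which preserves loss values exactly on constant regions) and placed at its
#' origin. The grid is non-overlapping, so no blending occurs; pixels not
#' covered by any kept patch stay zero with `valid_mask = 0`.
#'
#' @param maps list of patch heatmap matrices.
#' @param origins list/matrix of 0-based (row, col) source-window origins.
#' @param source_shape (H, W) of the source image.
#' @param source_size source window edge (130 by default).
#' @param scene_id,metric provenance recorded on the result.
#' @return object of class `image_heatmap`: `values` (H x W, >= 0),
#'   `valid_mask` (H x W 0/1), `scene_id`, `metric`.
#' @export
assemble_image_heatmap <- function(maps, origins, source_shape,
                                   source_size = 130L, scene_id = "scene",
                                   metric = "mse") {
  H <- source_shape[1]; W <- source_shape[2]
  if (is.matrix(origins)) origins <- lapply(seq_len(nrow(origins)),
                                            function(i) origins[i, ])
  check_that(length(maps) == length(origins),
             "need one origin per patch map")
  values <- matrix(0, H, W)
  valid <- matrix(0, H, W)
  for (i in seq_along(maps)) {
    o <- origins[[i]]
    check_that(all(o >= 0) && o[1] + source_size <= H && o[2] + source_size <= W,
               sprintf("patch origin (%d,%d) outside image bounds", o[1], o[2]))
    rows <- (o[1] + 1):(o[1] + source_size)
    cols <- (o[2] + 1):(o[2] + source_size)
    check_that(all(valid[rows, cols] == 0),
               "overlapping patch windows violate the non-overlap contract",
               class = "berryvae_contract_error")
    up <- resize_nearest(maps[[i]], source_size, source_size)
    values[rows, cols] <- up
    valid[rows, cols] <- 1
  }
  check_that(all(is.finite(values)), "heatmap values must be finite",
             class = "berryvae_numeric_error")
  structure(list(values = values, valid_mask = valid, scene_id = scene_id,
                 metric = metric),
            class = "image_heatmap")
}

#' Full-image anomaly heatmap from a trained model
#'
#' Extracts the patch grid from the image and ROI mask, reconstructs every
#' kept patch, and assembles the per-patch loss maps into an image heatmap.
#'
#' @param model trained `berry_model`.
#' @param image H x W x 3 array.
#' @param roi_mask H x W 0/1 region-of-interest mask.
#' @param metric pixel loss for the maps.
#' @param patch_size,coverage_threshold see [extract_patches()].
#' @param scene_id provenance tag.
#' @return an `image_heatmap`.
#' @export
model_heatmap <- function(model, image, roi_mask, metric = "mse",
                          patch_size = 130L, coverage_threshold = 0.1,
                          scene_id = "scene") {
  check_that(isTRUE(model$trained) ,
             "model is untrained; train or load a checkpoint first",
             class = "berryvae_state_error")
  ps <- extract_patches(image, roi_mask, patch_size, coverage_threshold,
                        target_size = model$config$input_size,
                        scene_id = scene_id)
  if (length(ps$patches) == 0)
    return(assemble_image_heatmap(list(), list(), dim(image)[1:2],
                                  patch_size, scene_id, metric))
  recs <- reconstruct(model, ps$patches)
  maps <- lapply(seq_along(ps$patches), function(i)
    patch_heatmap(ps$patches[[i]]$pixels, recs[[i]], metric))
  assemble_image_heatmap(maps, lapply(ps$patches, function(p) p$origin),
                         dim(image)[1:2], patch_size, scene_id, metric)
}

#' Remove small connected heat blobs
#'
#' Optional post-filter: zeroes connected components of above-threshold heat
#' smaller than `min_pixels` (suppresses single-pixel false positives at
#' berry borders). Off by default in the pipeline.
#'
#' @param heatmap an `image_heatmap`.
#' @param threshold heat level defining a detection.
#' @param min_pixels minimum component size to keep.
#' @return the filtered `image_heatmap`.
#' @export
suppress_small_blobs <- function(heatmap, threshold, min_pixels = 20L) {
  hot <- (heatmap$values > threshold) * 1
  if (!any(hot > 0)) return(heatmap)
  lab <- label_components(hot)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_pixels)
  if (length(drop)) heatmap$values[lab %in% drop] <- 0
  heatmap
}

# dark blue -> cyan -> yellow -> red colour scale
heat_colormap <- function(n = 256) {
  ramp <- grDevices::colorRamp(c("#00004B", "#0050FF", "#00D0D0",
                                 "#FFE000", "#FF2000"), space = "rgb")
  ramp(seq(0, 1, length.out = n)) / 255
}

#' Render a heatmap overlay on its source image
#'
#' Blends a colour-mapped heatmap (red = anomalous, dark blue = healthy)
#' over the image inside the valid mask; invalid pixels show the image
#' unchanged.
#'
#' @param heatmap an `image_heatmap`.
#' @param image the H x W x 3 source image.
#' @param normalization `"minmax"` (per image) or `"fixed"` (absolute scale
#'   via `max_value`, for cross-image comparability).
#' @param max_value upper heat value for `"fixed"` normalisation.
#' @param alpha overlay opacity in \[0,1\].
#' @param file optional PNG output path.
#' @return H x W x 3 RGB array with attribute `normalization`; written to
#'   `file` when given.
#' @export
render_overlay <- function(heatmap, image, normalization = c("minmax", "fixed"),
                           max_value = NULL, alpha = 0.6, file = NULL) {
  normalization <- match.arg(normalization)
  check_that(all(dim(image)[1:2] == dim(heatmap$values)),
             "heatmap and image shapes differ")
  v <- heatmap$values
  hi <- if (normalization == "fixed") {
    check_that(!is.null(max_value) && max_value > 0,
               "fixed normalisation needs a positive max_value")
    max_value
  } else max(v[heatmap$valid_mask > 0], 0)
  scaled <- if (hi > 0) pmin(v / hi, 1) else v * 0
  cmap <- heat_colormap()
  idx <- pmin(pmax(round(scaled * 255) + 1, 1), 256)
  out <- image
  a <- alpha * (heatmap$valid_mask > 0)
  for (c in 1:3) {
    heat_c <- matrix(cmap[idx, c], nrow(v), ncol(v))
    out[, , c] <- (1 - a) * image[, , c] + a * heat_c
  }
  out <- clamp01(out)
  attr(out, "normalization") <- normalization
  if (!is.null(file)) write_image_png(out, file)
  out
}

#' @export
print.image_heatmap <- function(x, ...) {
  cat(sprintf("<image_heatmap %s %dx%d metric=%s covered=%.0f%% max=%.4g>\n",
              x$scene_id, nrow(x$values), ncol(x$values), x$metric,
              100 * mean(x$valid_mask), max(x$values)))
  invisible(x)
}
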