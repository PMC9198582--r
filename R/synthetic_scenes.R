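# Synthetic berry scenes with ground-truth masks.
#
# Scenes emulate field images of grapevine bunches: clustered quasi-circular
# green berries (two colour/size regimes standing in for the BBCH75 and
# BBCH89 growth stages), smooth illumination variation, and injected
# anomalies (discoloration, withering texture, thin stem-like structures).
# Every scene carries a berry mask and an anomaly mask, so each downstream
# stage is testable without field data.

#' Specification of a synthetic berry scene
#'
#' @param height,width scene size in pixels.
#' @param berry_count_range (min, max) berries per fully covered 130x130
#'   window; the generator calibrates its berry spacing to hit this density.
#' @param berry_radius_range (min, max) berry radius in pixels; `NULL` picks
#'   the stage-specific default (12-16 early, 15-20 late).
#' @param stage_tag `"early"` (pea-sized, saturated green) or `"late"`
#'   (pre-harvest, larger, yellow-green) colour/size regime.
#' @param background_tone background RGB triple in \[0,1\].
#' @param illumination_sigma relative amplitude of the smooth multiplicative
#'   illumination field (0 = uniform lighting).
#' @param anomaly_fraction fraction of berries receiving an injected anomaly,
#'   in \[0,1\].
#' @param anomaly_kinds subset of `c("discolor", "wither", "stem")`.
#' @param seed integer seed; identical (spec, seed) reproduce a scene
#'   bit-for-bit.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(height = 390L, width = 390L,
                       berry_count_range = c(6L, 10L),
                       berry_radius_range = NULL,
                       stage_tag = c("early", "late"),
                       background_tone = c(0.36, 0.30, 0.26),
                       illumination_sigma = 0.08,
                       anomaly_fraction = 0,
                       anomaly_kinds = c("discolor", "wither", "stem"),
                       seed = 1L) {
  stage_tag <- match.arg(stage_tag)
  if (is.null(berry_radius_range))
    berry_radius_range <- if (stage_tag == "early") c(12, 16) else c(15, 20)
  check_that(height > 0 && width > 0,
             "scene dimensions must be strictly positive: height/width")
  check_that(berry_count_range[1] <= berry_count_range[2] &&
             all(berry_count_range >= 0),
             "berry_count_range must be ordered and non-negative")
  check_that(berry_radius_range[1] <= berry_radius_range[2] &&
             all(berry_radius_range > 0),
             "berry_radius_range must be ordered and strictly positive")
  check_that(anomaly_fraction >= 0 && anomaly_fraction <= 1,
             "anomaly_fraction must lie in [0,1]")
  check_that(illumination_sigma >= 0, "illumination_sigma must be >= 0")
  check_that(all(anomaly_kinds %in% c("discolor", "wither", "stem")),
             "anomaly_kinds must be a subset of discolor/wither/stem")
  check_that(all(background_tone >= 0 & background_tone <= 1),
             "background_tone must be an RGB triple in [0,1]")
  structure(list(height = as.integer(height), width = as.integer(width),
                 berry_count_range = berry_count_range,
                 berry_radius_range = berry_radius_range,
                 stage_tag = stage_tag, background_tone = background_tone,
                 illumination_sigma = illumination_sigma,
                 anomaly_fraction = anomaly_fraction,
                 anomaly_kinds = anomaly_kinds, seed = as.integer(seed)),
            class = "scene_spec")
}

stage_palette <- function(stage_tag) {
  if (stage_tag == "early")
    list(h = 0.30, s = 0.60, v = 0.52, h_jit = 0.02, v_jit = 0.06)
  else
    list(h = 0.22, s = 0.50, v = 0.66, h_jit = 0.015, v_jit = 0.06)
}

#' Generate a synthetic labelled berry scene
#'
#' Renders anti-aliased shaded berries on a jittered grid whose spacing is
#' calibrated so that a fully covered 130x130 window holds a berry count in
#' the configured range, multiplies in a smooth random illumination field,
#' and injects anomalies into the requested fraction of berries.
#'
#' @param spec a [scene_spec()].
#' @param scene_id identifier stored on the scene.
#' @return object of class `labeled_scene` with fields `image` (H x W x 3 in
#'   \[0,1\]), `berry_mask`, `anomaly_mask` (0/1 matrices), `stage_tag`,
#'   `scene_id`, `seed`.
#' @export
generate_scene <- function(spec, scene_id = "scene") {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  scene <- with_seed(spec$seed, {
    img <- render_background(spec)
    berry_mask <- matrix(0, H, W)
    centers <- NULL
    if (spec$berry_count_range[2] > 0) {
      target <- runif(1, spec$berry_count_range[1], spec$berry_count_range[2])
      spacing <- 130 / sqrt(target)
      gx <- seq(spacing / 2, W - spacing / 4, by = spacing)
      gy <- seq(spacing / 2, H - spacing / 4, by = spacing)
      pal <- stage_palette(spec$stage_tag)
      pts <- expand.grid(y = gy, x = gx)
      pts$x <- pts$x + (match(pts$y, gy) %% 2) * spacing / 2   # hex offset
      pts$x <- pts$x + runif(nrow(pts), -0.22, 0.22) * spacing
      pts$y <- pts$y + runif(nrow(pts), -0.22, 0.22) * spacing
      pts <- pts[pts$x >= 2 & pts$x <= W - 1 & pts$y >= 2 & pts$y <= H - 1, ]
      ord <- order(pts$y)
      centers <- matrix(0, nrow(pts), 2)
      for (k in seq_len(nrow(pts))) {
        i <- ord[k]
        r <- runif(1, spec$berry_radius_range[1], spec$berry_radius_range[2])
        col <- grDevices::hsv(
          h = min(max(pal$h + runif(1, -pal$h_jit, pal$h_jit), 0), 1),
          s = min(max(pal$s + runif(1, -0.08, 0.08), 0), 1),
          v = min(max(pal$v + runif(1, -pal$v_jit, pal$v_jit), 0), 1))
        rgbcol <- as.numeric(grDevices::col2rgb(col)) / 255
        res <- render_berry(img, berry_mask, pts$y[i], pts$x[i], r, rgbcol)
        img <- res$img
        berry_mask <- res$mask
        centers[k, ] <- c(pts$y[i], pts$x[i])
      }
    }
    if (spec$illumination_sigma > 0) {
      field <- matrix(rnorm(H * W), H, W)
      field <- blur_gaussian(field, sigma = min(H, W) / 8)
      field <- field / max(stats::sd(field), 1e-9)
      img <- img * array(rep(1 + spec$illumination_sigma * field, 3), c(H, W, 3))
      img <- clamp01(img)
    }
    sc <- structure(list(image = img, berry_mask = berry_mask,
                         anomaly_mask = matrix(0, H, W),
                         stage_tag = spec$stage_tag, scene_id = scene_id,
                         seed = spec$seed),
                    class = "labeled_scene")
    if (spec$anomaly_fraction > 0 && !is.null(centers) && nrow(centers) > 0) {
      n_anom <- max(1L, round(spec$anomaly_fraction * nrow(centers)))
      lab <- label_components(sc$berry_mask)
      comp_ids <- setdiff(unique(as.integer(lab)), 0L)
      n_anom <- min(n_anom, length(comp_ids))
      picks <- sample(comp_ids, n_anom)
      kinds <- sample(spec$anomaly_kinds, n_anom, replace = TRUE)
      for (k in seq_len(n_anom))
        sc <- inject_anomaly(sc, kinds[k],
                             seed = sample.int(.Machine$integer.max, 1),
                             component = picks[k], labels = lab)
    }
    sc
  })
  scene
}

render_background <- function(spec) {
  H <- spec$height; W <- spec$width
  tex <- blur_gaussian(matrix(rnorm(H * W), H, W), 2.5)
  tex <- tex / max(stats::sd(tex), 1e-9)
  img <- array(0, c(H, W, 3))
  for (c in 1:3) img[, , c] <- spec$background_tone[c] * (1 + 0.06 * tex)
  clamp01(img)
}

# draw one shaded, slightly elliptic, anti-aliased berry into img/mask
render_berry <- function(img, mask, cy, cx, r, rgbcol) {
  H <- nrow(mask); W <- ncol(mask)
  ar <- runif(1, 0.88, 1.0)                 # minor/major axis ratio
  th <- runif(1, 0, pi)
  pad <- ceiling(r / min(ar, 1)) + 2
  y0 <- max(1, floor(cy - pad)); y1 <- min(H, ceiling(cy + pad))
  x0 <- max(1, floor(cx - pad)); x1 <- min(W, ceiling(cx + pad))
  yy <- matrix((y0:y1) - cy, y1 - y0 + 1, x1 - x0 + 1)
  xx <- matrix((x0:x1) - cx, y1 - y0 + 1, x1 - x0 + 1, byrow = TRUE)
  u <- cos(th) * xx + sin(th) * yy
  v <- -sin(th) * xx + cos(th) * yy
  d <- sqrt((u / 1)^2 + (v / ar)^2)
  cov <- pmin(pmax((r - d) + 0.5, 0), 1)    # ~1 px anti-aliased edge
  sh <- 1 - 0.35 * pmin(d / r, 1)^2         # radial shading
  hx <- -0.35 * r; hy <- -0.35 * r          # diffuse sheen, upper-left
  spec_hl <- 0.14 * exp(-((xx - hx)^2 + (yy - hy)^2) / (2 * (0.45 * r)^2))
  for (c in 1:3) {
    base <- img[y0:y1, x0:x1, c]
    col <- pmin(rgbcol[c] * sh + spec_hl, 1)
    img[y0:y1, x0:x1, c] <- (1 - cov) * base + cov * col
  }
  mask[y0:y1, x0:x1] <- pmax(mask[y0:y1, x0:x1], (cov > 0.5) * 1)
  list(img = img, mask = mask)
}

#' Inject an anomaly into a scene
#'
#' Alters a connected sub-region of one berry (`discolor`: colour shift
#' toward brown; `wither`: darkening plus high-frequency texture) or draws a
#' thin elongated stem-like structure near the berries (`stem`). The
#' anomaly mask of the returned scene marks exactly the altered pixels.
#'
#' @param scene a `labeled_scene`.
#' @param kind `"discolor"`, `"wither"` or `"stem"`.
#' @param seed integer seed for the anomaly's own RNG stream.
#' @param component optional berry component id to target (internal use).
#' @param labels optional precomputed component labelling of the berry mask.
#' @return a new `labeled_scene` with updated image and anomaly mask.
#' @export
inject_anomaly <- function(scene, kind = c("discolor", "wither", "stem"),
                           seed = 1L, component = NULL, labels = NULL) {
  stopifnot(inherits(scene, "labeled_scene"))
  kind <- match.arg(kind)
  if (kind %in% c("discolor", "wither"))
    check_that(any(scene$berry_mask > 0),
               paste(kind, "anomaly requires at least one berry in the scene"),
               class = "berryvae_precondition_error")
  with_seed(seed, {
    H <- nrow(scene$berry_mask); W <- ncol(scene$berry_mask)
    if (kind == "stem") {
      stroke <- draw_stem_mask(scene$berry_mask)
      target <- stroke
      col <- c(0.30, 0.21, 0.11)
      wmix <- 0.85
      img <- scene$image
      for (c in 1:3)
        img[, , c][target > 0] <-
          (1 - wmix) * img[, , c][target > 0] + wmix * col[c]
    } else {
      if (is.null(labels)) labels <- label_components(scene$berry_mask)
      ids <- setdiff(unique(as.integer(labels)), 0L)
      if (is.null(component)) component <- sample(ids, 1)
      comp <- labels == component
      target <- berry_subregion(comp, frac = runif(1, 0.2, 0.8))
      img <- scene$image
      if (kind == "discolor") {
        # luminance-preserving hue shift toward rot-brown: the berry keeps
        # its shading and sheen, only the colour turns
        sel <- target > 0
        lum <- 0.30 * img[, , 1][sel] + 0.59 * img[, , 2][sel] +
          0.11 * img[, , 3][sel]
        tint <- c(1.46, 0.88, 0.41)   # brown ratios, unit luminance
        for (c in 1:3)
          img[, , c][sel] <- clamp01(tint[c] * lum)
      } else {  # wither
        n_t <- sum(target > 0)
        tex <- 0.12 * rnorm(n_t)
        for (c in 1:3)
          img[, , c][target > 0] <-
            clamp01(img[, , c][target > 0] * 0.45 + 0.04 + tex)
      }
    }
    # guarantee the pixel diff is nonzero exactly on the target mask
    sel <- target > 0
    for (c in 1:3) {
      ch_new <- img[, , c][sel]; ch_old <- scene$image[, , c][sel]
      same <- ch_new == ch_old
      if (any(same))
        ch_new[same] <- ifelse(ch_old[same] > 0.5, ch_old[same] - 1 / 255,
                               ch_old[same] + 1 / 255)
      img[, , c][sel] <- ch_new
    }
    scene$image <- img
    scene$anomaly_mask <- pmax(scene$anomaly_mask, target)
    scene
  })
}

# connected sub-region of one berry component covering roughly `frac` of it
berry_subregion <- function(comp, frac) {
  idx <- which(comp, arr.ind = TRUE)
  y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
  x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
  sub <- comp[y0:y1, x0:x1, drop = FALSE]
  noise <- blur_gaussian(matrix(rnorm(length(sub)), nrow(sub)), 3)
  vals <- noise[sub]
  thr <- stats::quantile(vals, 1 - frac)
  blob <- sub & noise >= thr
  if (sum(blob) < 8) blob <- sub                     # degenerate: whole berry
  lab <- label_components(blob * 1)
  if (max(lab) > 1) {                                # keep the largest piece
    sizes <- tabulate(lab[lab > 0])
    blob <- lab == which.max(sizes)
  }
  out <- matrix(0, nrow(comp), ncol(comp))
  out[y0:y1, x0:x1] <- blob * 1
  out
}

# thin (2-4 px) gently curved stroke hugging the berry region when berries
# exist, free-floating otherwise
draw_stem_mask <- function(berry_mask) {
  H <- nrow(berry_mask); W <- ncol(berry_mask)
  has_berries <- any(berry_mask > 0)
  near <- if (has_berries) dilate_mask(berry_mask, 12) else NULL
  if (has_berries) {
    idx <- which(berry_mask > 0, arr.ind = TRUE)
    st <- idx[sample(nrow(idx), 1), ]
    y <- st[1]; x <- st[2]
  } else {
    y <- runif(1, H * 0.25, H * 0.75); x <- runif(1, W * 0.25, W * 0.75)
  }
  len <- round(runif(1, 40, min(80, H, W)))
  width <- runif(1, 2, 4)
  ang <- runif(1, 0, 2 * pi)
  curv <- runif(1, -0.02, 0.02)
  pts <- matrix(0, len, 2)
  for (i in seq_len(len)) {
    pts[i, ] <- c(y, x)
    ang <- ang + curv + rnorm(1, 0, 0.03)
    yn <- y + sin(ang); xn <- x + cos(ang)
    if (yn < 2 || yn > H - 1 || xn < 2 || xn > W - 1) { ang <- ang + pi / 2; next }
    if (has_berries && near[round(yn), round(xn)] == 0) {
      # steer back toward the berry region
      tgt <- which(berry_mask > 0, arr.ind = TRUE)
      g <- tgt[sample(nrow(tgt), 1), ]
      ang <- atan2(g[1] - y, g[2] - x)
      yn <- y + sin(ang); xn <- x + cos(ang)
    }
    y <- yn; x <- xn
  }
  mask <- matrix(0, H, W)
  r <- width / 2
  pr <- ceiling(r) + 1
  for (i in seq_len(nrow(pts))) {
    cy <- pts[i, 1]; cx <- pts[i, 2]
    ys <- max(1, floor(cy - pr)):min(H, ceiling(cy + pr))
    xs <- max(1, floor(cx - pr)):min(W, ceiling(cx + pr))
    dd <- outer((ys - cy)^2, (xs - cx)^2, "+")
    mask[ys, xs][dd <= r^2] <- 1
  }
  mask
}

#' Generate a collection of labelled scenes
#'
#' Returns `n_healthy` scenes with empty anomaly masks followed by
#' `n_anomalous` scenes with non-empty ones. Stage tags alternate within
#' each group, so both groups are balanced across the two regimes within
#' one scene. Each scene derives its own seed from the collection seed and
#' its index, so generation order does not matter.
#'
#' @param n_healthy,n_anomalous scene counts (>= 0).
#' @param spec base [scene_spec()]; its `stage_tag` is overridden by the
#'   balancing and `anomaly_fraction` is forced to 0 for healthy scenes; for
#'   anomalous scenes a spec value of 0 falls back to 0.35 (roughly a third
#'   of the berries damaged — the visibly-damaged-bunch regime).
#' @param seed collection seed.
#' @return list of `labeled_scene` objects.
#' @export
generate_dataset <- function(n_healthy, n_anomalous, spec = scene_spec(),
                             seed = 1L) {
  check_that(n_healthy >= 0 && n_anomalous >= 0, "scene counts must be >= 0")
  stages <- c("early", "late")
  make <- function(i, healthy) {
    st <- stages[(i - 1) %% 2 + 1]
    sp <- scene_spec(
      height = spec$height, width = spec$width,
      berry_count_range = spec$berry_count_range,
      berry_radius_range = NULL,   # stage-specific default sizes
      stage_tag = st, background_tone = spec$background_tone,
      illumination_sigma = spec$illumination_sigma,
      anomaly_fraction = if (healthy) 0 else
        if (spec$anomaly_fraction > 0) spec$anomaly_fraction else 0.35,
      anomaly_kinds = spec$anomaly_kinds,
      seed = derive_seed(seed, i + if (healthy) 0 else 1000000L))
    generate_scene(sp, scene_id = sprintf("%s%04d",
                                          if (healthy) "h" else "a", i))
  }
  c(lapply(seq_len(n_healthy), make, healthy = TRUE),
    lapply(seq_len(n_anomalous), make, healthy = FALSE))
}

#' Write scenes to disk as PNG triplets plus a JSON manifest
#'
#' Each scene becomes `<id>.png` (RGB image), `<id>.berry.png` and
#' `<id>.anomaly.png` (8-bit 0/255 masks); `manifest.json` records scene_id,
#' stage_tag, label and seed.
#'
#' @param scenes list of `labeled_scene`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_scene_set <- function(scenes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(scenes, function(sc) {
    write_image_png(sc$image, file.path(dir, paste0(sc$scene_id, ".png")))
    write_mask_png(sc$berry_mask, file.path(dir, paste0(sc$scene_id, ".berry.png")))
    write_mask_png(sc$anomaly_mask,
                   file.path(dir, paste0(sc$scene_id, ".anomaly.png")))
    list(scene_id = sc$scene_id, stage_tag = sc$stage_tag,
         label = if (sum(sc$anomaly_mask) > 0) "anomalous" else "healthy",
         seed = sc$seed)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a scene set written by [write_scene_set()]
#'
#' @param dir directory holding the PNG triplets and `manifest.json`.
#' @return list of `labeled_scene` objects.
#' @export
load_scene_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(seq_len(nrow(man)), function(i) {
    id <- man$scene_id[i]
    structure(list(
      image = read_image_png(file.path(dir, paste0(id, ".png"))),
      berry_mask = read_mask_png(file.path(dir, paste0(id, ".berry.png"))),
      anomaly_mask = read_mask_png(file.path(dir, paste0(id, ".anomaly.png"))),
      stage_tag = man$stage_tag[i], scene_id = id, seed = man$seed[i]),
      class = "labeled_scene")
  })
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("<labeled_scene %s %dx%d stage=%s berries=%.0f%% anomalies=%d px>\n",
              x$scene_id, nrow(x$berry_mask), ncol(x$berry_mask), x$stage_tag,
              100 * mean(x$berry_mask), sum(x$anomaly_mask)))
  invisible(x)
}
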