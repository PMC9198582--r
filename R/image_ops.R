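# Low-level image primitives shared across modules.
#
# Images are R arrays of dim (H, W, C) with values in [0, 1]; masks are H x W
# matrices of 0/1. Batches handed to the network are D x N matrices where each
# column is `as.numeric()` of such an array (h fastest, then w, then c).

batch_from_arrays <- function(arrs) {
  d <- length(arrs[[1]])
  vapply(arrs, function(a) as.numeric(a), numeric(d))
}

array_from_flat <- function(v, H, W, C = 3) array(v, dim = c(H, W, C))

#' Area-averaging image resize
#'
#' Resizes an image (or single-channel matrix) with exact box-filter area
#' averaging, the mean-preserving choice for downsampling. Implemented as a
#' pair of sparse row/column weight matrices, so a constant image stays
#' constant and the global mean is conserved.
#'
#' @param img matrix (H x W) or array (H x W x C) of reals.
#' @param out_h,out_w target size in pixels.
#' @return resized matrix or array with values in the input range.
#' @export
resize_area <- function(img, out_h, out_w) {
  resize_1d <- function(n_in, n_out) {
    # weight matrix n_out x n_in of fractional interval overlaps
    Wm <- matrix(0, n_out, n_in)
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * scale
      hi <- i * scale
      j0 <- floor(lo) + 1
      j1 <- ceiling(hi)
      for (j in j0:min(j1, n_in)) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) Wm[i, j] <- ov
      }
    }
    Wm / scale
  }
  if (is.matrix(img)) {
    Wr <- resize_1d(nrow(img), out_h)
    Wc <- resize_1d(ncol(img), out_w)
    return(Wr %*% img %*% t(Wc))
  }
  Wr <- resize_1d(dim(img)[1], out_h)
  Wc <- resize_1d(dim(img)[2], out_w)
  out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- Wr %*% img[, , c] %*% t(Wc)
  out
}

#' Nearest-neighbour image resize
#'
#' @param img matrix or H x W x C array.
#' @param out_h,out_w target size in pixels.
#' @return resized image; values are copies of input values (no interpolation).
#' @export
resize_nearest <- function(img, out_h, out_w) {
  h_in <- if (is.matrix(img)) nrow(img) else dim(img)[1]
  w_in <- if (is.matrix(img)) ncol(img) else dim(img)[2]
  ri <- pmin(h_in, floor((seq_len(out_h) - 0.5) * h_in / out_h) + 1)
  ci <- pmin(w_in, floor((seq_len(out_w) - 0.5) * w_in / out_w) + 1)
  if (is.matrix(img)) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

# Separable Gaussian blur with edge-renormalised weights (row-stochastic, so
# constants are preserved exactly).
gauss_weights <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  Wm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    keep <- j >= 1 & j <= n
    Wm[i, j[keep]] <- k[keep]
    Wm[i, ] <- Wm[i, ] / sum(Wm[i, ])
  }
  Wm
}

blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (is.matrix(img)) {
    Gr <- gauss_weights(nrow(img), sigma)
    Gc <- gauss_weights(ncol(img), sigma)
    return(Gr %*% img %*% t(Gc))
  }
  Gr <- gauss_weights(dim(img)[1], sigma)
  Gc <- gauss_weights(dim(img)[2], sigma)
  out <- img
  for (c in seq_len(dim(img)[3])) out[, , c] <- Gr %*% img[, , c] %*% t(Gc)
  out
}

#' Binary dilation of a mask
#'
#' Iterated 8-neighbourhood dilation (square structuring element of the given
#' radius), adequate for the small radii used in containment checks.
#'
#' @param mask H x W matrix of 0/1.
#' @param radius dilation radius in pixels.
#' @return dilated 0/1 matrix.
#' @export
dilate_mask <- function(mask, radius) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(radius)) {
    sh <- m
    sh[-1, ] <- sh[-1, ] | m[-H, ]
    sh[-H, ] <- sh[-H, ] | m[-1, ]
    m2 <- sh
    m2[, -1] <- m2[, -1] | sh[, -W]
    m2[, -W] <- m2[, -W] | sh[, -1]
    m <- m2
  }
  m * 1
}

# Connected-component labelling (4-connectivity) by iterative minimum-label
# propagation; fine for the compact blobs that occur in berry masks.
label_components <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0, H, W)
  lab[m] <- seq_len(sum(m))
  big <- sum(m) + 1
  repeat {
    l <- lab
    l[!m] <- big
    up <- rbind(rep(big, W), l[-H, , drop = FALSE])
    dn <- rbind(l[-1, , drop = FALSE], rep(big, W))
    lf <- cbind(rep(big, H), l[, -W, drop = FALSE])
    rt <- cbind(l[, -1, drop = FALSE], rep(big, H))
    nl <- pmin(l, up, dn, lf, rt)
    nl[!m] <- 0
    if (all(nl == lab)) break
    lab <- nl
  }
  # compact label ids
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

component_elongation <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 3) return(1)
  ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12))
}

#' Read / write RGB images and binary masks as PNG
#'
#' Masks are stored 8-bit with 0/255 coding.
#'
#' @param path file path.
#' @param img H x W x 3 array in \[0,1\] (for `write_image_png`).
#' @param mask H x W 0/1 matrix (for `write_mask_png`).
#' @return `read_image_png` returns an H x W x 3 array; `read_mask_png` a 0/1
#'   matrix; writers return the path invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  a
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  (a > 0.5) * 1
}
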