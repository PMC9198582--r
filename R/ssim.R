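# Structural similarity (SSIM) with a Gaussian window, plus the analytic
# gradient with respect to the second image, so 1 - SSIM can serve as a
# training loss. Window weights are renormalised at image edges, keeping the
# local-moment operator row-stochastic: SSIM of two identical constants is
# exactly 1.

ssim_constants <- function(data_range, k1 = 0.01, k2 = 0.03)
  c(C1 = (k1 * data_range)^2, C2 = (k2 * data_range)^2)

# local averaging operator as row/column weight matrices
ssim_window_ops <- function(H, W, window, sigma) {
  half <- (window - 1) / 2
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  band <- function(n) {
    Wm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      keep <- j >= 1 & j <= n
      Wm[i, j[keep]] <- k[keep]
      Wm[i, ] <- Wm[i, ] / sum(Wm[i, ])
    }
    Wm
  }
  list(Gr = band(H), Gc = band(W))
}

#' Structural similarity index between two images
#'
#' Standard SSIM (Gaussian window, default 11 pixels / sigma 1.5), averaged
#' over pixels and channels. Symmetric in its arguments and equal to 1 iff
#' the images agree.
#'
#' @param x,x_hat images as H x W matrices or H x W x C arrays, same shape.
#' @param window odd window size in pixels.
#' @param data_range value range of the data (1 for \[0,1\] images).
#' @param sigma Gaussian window standard deviation.
#' @return scalar SSIM in \[-1, 1\].
#' @export
ssim <- function(x, x_hat, window = 11L, data_range = 1, sigma = 1.5) {
  H <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  W <- if (is.matrix(x)) ncol(x) else dim(x)[2]
  check_that(all((dim(x) %||% 0) == (dim(x_hat) %||% 0)),
             "x and x_hat must have the same shape")
  check_that(window <= H && window <= W,
             sprintf("SSIM window (%d) larger than image (%dx%d)", window, H, W))
  ops <- ssim_window_ops(H, W, window, sigma)
  cs <- ssim_constants(data_range)
  chans <- if (is.matrix(x)) list(list(x, x_hat)) else
    lapply(seq_len(dim(x)[3]), function(c) list(x[, , c], x_hat[, , c]))
  mean(vapply(chans, function(p)
    mean(ssim_channel(p[[1]], p[[2]], ops, cs)$S), numeric(1)))
}

ssim_channel <- function(X, Y, ops, cs) {
  B <- function(M) ops$Gr %*% M %*% t(ops$Gc)
  mu_x <- B(X); mu_y <- B(Y)
  mxx <- B(X * X); myy <- B(Y * Y); mxy <- B(X * Y)
  sx2 <- mxx - mu_x^2; sy2 <- myy - mu_y^2; sxy <- mxy - mu_x * mu_y
  A1 <- 2 * mu_x * mu_y + cs["C1"]; A2 <- 2 * sxy + cs["C2"]
  B1 <- mu_x^2 + mu_y^2 + cs["C1"]; B2 <- sx2 + sy2 + cs["C2"]
  list(S = (A1 * A2) / (B1 * B2),
       mu_x = mu_x, mu_y = mu_y, A1 = A1, A2 = A2, B1 = B1, B2 = B2, X = X, Y = Y)
}

# gradient of mean SSIM over one channel w.r.t. Y; gS is the upstream scalar
# weight applied uniformly (1 / (npix * nchan) for the overall mean)
ssim_channel_grad <- function(cc, ops, gS) {
  Bt <- function(M) t(ops$Gr) %*% M %*% ops$Gc
  den <- cc$B1 * cc$B2
  dS_dA1 <- cc$A2 / den
  dS_dA2 <- cc$A1 / den
  dS_dB1 <- -(cc$A1 * cc$A2) / (cc$B1^2 * cc$B2)
  dS_dB2 <- -(cc$A1 * cc$A2) / (cc$B1 * cc$B2^2)
  g_sxy <- gS * dS_dA2 * 2
  g_sy2 <- gS * dS_dB2
  g_mu_y <- gS * (dS_dA1 * 2 * cc$mu_x + dS_dB1 * 2 * cc$mu_y)
  # sxy = mxy - mu_x mu_y ; sy2 = myy - mu_y^2
  g_mxy <- g_sxy
  g_myy <- g_sy2
  g_mu_y <- g_mu_y - g_sxy * cc$mu_x - 2 * g_sy2 * cc$mu_y
  Bt(g_mu_y) + 2 * cc$Y * Bt(g_myy) + cc$X * Bt(g_mxy)
}

# mean SSIM and its gradient w.r.t. x_hat, for H x W x C arrays
ssim_with_grad <- function(x, x_hat, window = 11L, data_range = 1, sigma = 1.5) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  ops <- ssim_window_ops(H, W, window, sigma)
  cs <- ssim_constants(data_range)
  gS <- 1 / (H * W * C)
  grad <- array(0, dim = dim(x))
  total <- 0
  for (c in seq_len(C)) {
    cc <- ssim_channel(x[, , c], x_hat[, , c], ops, cs)
    total <- total + sum(cc$S) * gS
    grad[, , c] <- ssim_channel_grad(cc, ops, gS)
  }
  list(value = total, grad = grad)
}
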