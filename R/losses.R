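# Loss functions: feature perceptual loss, KL divergence of the latent
# Gaussian from the standard-normal prior, the weighted total objective,
# and the pixel-wise l1 / MSE / BCE loss maps used for scoring and heatmaps.

BCE_EPS <- 1e-7

#' Latent Gaussian distribution (mean and log-variance)
#'
#' The encoder output: per-sample mean and log-variance vectors of the
#' diagonal Gaussian q(z|X). Vectors describe a single sample; matrices hold
#' one sample per column.
#'
#' @param mean numeric vector, or matrix with samples in columns.
#' @param log_variance same shape as `mean`.
#' @return an object of class `latent_distribution`.
#' @export
latent_distribution <- function(mean, log_variance) {
  check_that(length(mean) == length(log_variance),
             "mean and log_variance must have identical length")
  check_that(all(is.finite(log_variance)) && all(is.finite(mean)),
             "latent distribution parameters must be finite",
             class = "berryvae_numeric_error")
  if (is.matrix(mean)) check_that(is.matrix(log_variance) &&
      all(dim(mean) == dim(log_variance)), "mean/log_variance dims differ")
  structure(list(mean = mean, log_variance = log_variance),
            class = "latent_distribution")
}

#' Kullback-Leibler divergence from the standard normal prior
#'
#' Closed form for a diagonal Gaussian \eqn{q = N(\mu, \sigma^2)} against
#' \eqn{N(0, I)}: \eqn{\frac12 \sum_i (\mu_i^2 + \sigma_i^2 - 1 -
#' \log\sigma_i^2)}. Always non-negative, zero iff \eqn{\mu = 0,\ \sigma = 1}.
#'
#' @param dist a [latent_distribution()].
#' @return a scalar for vector-valued distributions; a per-sample numeric
#'   vector when `dist` holds a matrix of samples in columns.
#' @export
kl_divergence <- function(dist) {
  stopifnot(inherits(dist, "latent_distribution"))
  mu <- dist$mean; lv <- dist$log_variance
  check_that(all(is.finite(mu)) && all(is.finite(lv)),
             "non-finite latent parameters", class = "berryvae_numeric_error")
  if (is.matrix(mu)) {
    0.5 * colSums(mu^2 + exp(lv) - 1 - lv)
  } else {
    0.5 * sum(mu^2 + exp(lv) - 1 - lv)
  }
}

#' Weighted total training objective
#'
#' `alpha * kl + lambda_ * rec`, the weighted sum of the KL term and the
#' reconstruction (perceptual) term.
#'
#' @param rec reconstruction loss (scalar).
#' @param kl KL divergence (scalar).
#' @param alpha,lambda_ non-negative weights.
#' @return scalar total loss.
#' @export
total_loss <- function(rec, kl, alpha = 1, lambda_ = 1) {
  check_that(alpha >= 0 && lambda_ >= 0, "loss weights must be non-negative")
  alpha * kl + lambda_ * rec
}

loss_breakdown <- function(reconstruction, kl, alpha, lambda_, per_layer) {
  structure(list(reconstruction = reconstruction, kl = kl,
                 total = alpha * kl + lambda_ * reconstruction,
                 alpha = alpha, lambda_ = lambda_, per_layer = per_layer),
            class = "loss_breakdown")
}

#' Feature perceptual loss between an image and its reconstruction
#'
#' Both images pass through the same frozen extractor; at every tapped layer
#' l with feature maps of size \eqn{C^l \times W^l \times H^l} the layer loss
#' is \eqn{\frac{1}{2 C^l W^l H^l} \sum_{c,w,h} (\delta(x)^l - \delta(\hat
#' x)^l)^2}, and the reconstruction loss is the sum over tapped layers.
#'
#' @param x,x_hat images as H x W x C arrays (same shape), or D x N batch
#'   matrices (one flattened image per column).
#' @param extractor a built [build_extractor()] object, or a
#'   [feature_extractor_spec()] (built on the fly).
#' @return list with `reconstruction` (scalar; batch mean), `per_layer`
#'   (named vector of layer losses, batch means) and `per_sample`
#'   (samples x layers matrix).
#' @export
feature_perceptual_loss <- function(x, x_hat, extractor) {
  if (inherits(extractor, "feature_extractor_spec"))
    extractor <- build_extractor(extractor,
      input_channels = if (is.matrix(x)) 3L else dim(x)[3])
  xb <- as_loss_batch(x)
  yb <- as_loss_batch(x_hat)
  check_that(all(dim(xb) == dim(yb)), "x and x_hat must have the same shape")
  fx <- extractor_forward(extractor, xb, keep_cache = FALSE)
  fy <- extractor_forward(extractor, yb, keep_cache = FALSE)
  L <- length(fx$features)
  per_sample <- matrix(0, ncol(xb), L)
  for (l in seq_len(L)) {
    d <- fx$dims[[l]]
    norm <- 2 * prod(d)
    per_sample[, l] <- colSums((fx$features[[l]] - fy$features[[l]])^2) / norm
  }
  colnames(per_sample) <- if (!is.null(extractor$tap_names))
    extractor$tap_names else paste0("layer", seq_len(L))
  per_layer <- colMeans(per_sample)
  list(reconstruction = sum(per_layer), per_layer = per_layer,
       per_sample = per_sample)
}

as_loss_batch <- function(x) {
  if (is.matrix(x)) return(x)                        # already D x N
  if (length(dim(x)) == 3) return(matrix(as.numeric(x), ncol = 1))
  abort_validation("expected an H x W x C array or a D x N batch matrix")
}

#' Pixel-wise loss map between an image and its reconstruction
#'
#' Elementwise l1 `|x - xhat|`, squared error `(x - xhat)^2`, or binary cross
#' entropy `-(x log xhat + (1-x) log(1-xhat))` (inputs clamped to
#' `[1e-7, 1 - 1e-7]` for BCE), averaged over channels into one H x W map.
#' The patch score is the spatial mean of that map.
#'
#' @param x,x_hat H x W x C arrays (or H x W matrices) of the same shape.
#' @param metric one of `"l1"`, `"mse"`, `"bce"`.
#' @return list with `map` (H x W matrix) and `score` (scalar mean).
#' @export
pixel_loss_map <- function(x, x_hat, metric = c("l1", "mse", "bce")) {
  if (length(metric) != 1 || !metric %in% c("l1", "mse", "bce"))
    abort_validation(paste("unknown loss metric:", paste(metric, collapse = "/")),
                     class = "berryvae_config_error")
  check_that(length(x) == length(x_hat) &&
             all((dim(x) %||% length(x)) == (dim(x_hat) %||% length(x_hat))),
             "x and x_hat must have the same shape")
  per_elem <- switch(metric,
    l1 = abs(x - x_hat),
    mse = (x - x_hat)^2,
    bce = {
      xc <- pmin(pmax(x, BCE_EPS), 1 - BCE_EPS)
      yc <- pmin(pmax(x_hat, BCE_EPS), 1 - BCE_EPS)
      -(xc * log(yc) + (1 - xc) * log(1 - yc))
    })
  map <- if (length(dim(x)) == 3) {
    m <- per_elem[, , 1]
    for (c in seq_len(dim(x)[3])[-1]) m <- m + per_elem[, , c]
    m / dim(x)[3]
  } else {
    per_elem
  }
  list(map = map, score = mean(map))
}
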