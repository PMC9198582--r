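# Model architectures: the feature-perceptual variational autoencoder
# (FPL-VAE) and the baseline convolutional autoencoders (SSIM-AE / FPL-AE)
# sharing one encoder/decoder contract.
#
# FPL-VAE: encoder = 4 x (4x4 conv, stride 2, zero pad 1) + batch norm +
# LeakyReLU, reducing 64x64 input to a 4x4 map; two fully connected heads
# give the latent mean and log-variance. Decoder = fully connected expansion
# to 4x4, then 4 x (nearest-neighbour x2 upsample, 3x3 conv stride 1 with
# replication padding, batch norm, LeakyReLU) and a final 3x3 conv squashed
# through a sigmoid so outputs live in [0,1].
#
# Baseline AE: 4 encoder and 4 decoder conv layers, 3x3 kernels, padding 1,
# stride 1 (no spatial downsampling), batch norm + LeakyReLU; compression
# happens by channel narrowing through a middle bottleneck layer.

#' Configuration of the variational autoencoder
#'
#' @param input_size input patch edge in pixels (must be divisible by 16; the
#'   four stride-2 stages reduce it 16-fold to the bottleneck map).
#' @param input_channels image channels.
#' @param encoder_channels widths of the four encoder stages.
#' @param latent_dim latent dimensionality (>= 1).
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @param decoder_channels widths of the four decoder stages.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(input_size = 64L, input_channels = 3L,
                       encoder_channels = c(32L, 64L, 128L, 256L),
                       latent_dim = 100L, leaky_slope = 0.2,
                       decoder_channels = c(128L, 64L, 32L, 16L)) {
  check_that(length(encoder_channels) == 4 && length(decoder_channels) == 4,
             "encoder_channels and decoder_channels must have length 4")
  check_that(input_size %% 16 == 0 && input_size >= 16,
             "input_size must be a positive multiple of 16 (four stride-2 halvings)")
  check_that(latent_dim >= 1, "latent_dim must be >= 1")
  structure(list(input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 encoder_channels = as.integer(encoder_channels),
                 latent_dim = as.integer(latent_dim),
                 leaky_slope = leaky_slope,
                 decoder_channels = as.integer(decoder_channels)),
            class = "vae_config")
}

#' Configuration of the baseline autoencoder
#'
#' @param conv_channels widths of the four stride-1 conv layers (encoder and,
#'   mirrored, decoder).
#' @param kernel,padding,stride conv geometry (3 / 1 / 1).
#' @param bottleneck_channels width of the channel-narrowing middle layer
#'   that provides the compression.
#' @param input_size,input_channels,leaky_slope as in [vae_config()].
#' @return object of class `ae_config`.
#' @export
ae_config <- function(conv_channels = c(32L, 32L, 32L, 32L), kernel = 3L,
                      padding = 1L, stride = 1L, bottleneck_channels = 8L,
                      input_size = 64L, input_channels = 3L,
                      leaky_slope = 0.2) {
  check_that(length(conv_channels) == 4, "conv_channels must have length 4")
  check_that(stride == 1 && padding == (kernel - 1) / 2,
             "baseline AE uses stride 1 and 'same' padding")
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), padding = as.integer(padding),
                 stride = as.integer(stride),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 leaky_slope = leaky_slope),
            class = "ae_config")
}

#' Build an anomaly-detection model
#'
#' @param kind `"fpl_vae"` (variational, feature perceptual loss),
#'   `"fpl_ae"` (deterministic baseline, feature perceptual loss) or
#'   `"ssim_ae"` (deterministic baseline, 1 - SSIM loss).
#' @param config a [vae_config()] for `fpl_vae`, an [ae_config()] otherwise.
#' @param seed integer seed for weight initialisation.
#' @return object of class `berry_model`.
#' @export
build_model <- function(kind = c("fpl_vae", "fpl_ae", "ssim_ae"),
                        config = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(config))
    config <- if (kind == "fpl_vae") vae_config() else ae_config()
  if (kind == "fpl_vae") {
    stopifnot(inherits(config, "vae_config"))
    m <- with_seed(seed, build_vae_layers(config))
  } else {
    stopifnot(inherits(config, "ae_config"))
    m <- with_seed(seed, build_ae_layers(config))
  }
  m$kind <- kind
  m$config <- config
  m$seed <- as.integer(seed)
  m$trained <- FALSE
  class(m) <- c(kind, "berry_model")
  m
}

build_vae_layers <- function(cfg) {
  d <- c(cfg$input_size, cfg$input_size, cfg$input_channels)
  enc <- list()
  for (i in 1:4) {
    cv <- layer_conv(d, cfg$encoder_channels[i], kernel = 4, stride = 2,
                     pad = 1, pad_mode = "zero")
    d <- cv$out_dim
    enc <- c(enc, list(cv, layer_bn(d), layer_lrelu(d, cfg$leaky_slope)))
  }
  # encoder bottleneck map is (input_size/16)^2 x last width; assert it
  stopifnot(d[1] == cfg$input_size / 16, d[2] == cfg$input_size / 16)
  feat_n <- prod(d)
  fc_mu <- layer_fc(feat_n, cfg$latent_dim)
  fc_logvar <- layer_fc(feat_n, cfg$latent_dim)
  # start with a low posterior variance (sigma ~ e^-2): with the normalised
  # perceptual loss the reconstruction gradient on sigma is weak, and a unit
  # sigma at init floods z = mu + sigma*eps with noise, which teaches the
  # decoder to ignore the latent code altogether
  fc_logvar$b <- rep(-4, cfg$latent_dim)
  dec_fc <- layer_fc(cfg$latent_dim, feat_n)
  dd <- d
  dec <- list(layer_lrelu(dd, cfg$leaky_slope))
  for (i in 1:4) {
    up <- layer_upsample2(dd); dd <- up$out_dim
    cv <- layer_conv(dd, cfg$decoder_channels[i], kernel = 3, stride = 1,
                     pad = 1, pad_mode = "replicate")
    dd <- cv$out_dim
    dec <- c(dec, list(up, cv, layer_bn(dd), layer_lrelu(dd, cfg$leaky_slope)))
  }
  out_cv <- layer_conv(dd, cfg$input_channels, kernel = 3, stride = 1,
                       pad = 1, pad_mode = "replicate")
  dec <- c(dec, list(out_cv, layer_sigmoid(out_cv$out_dim)))
  list(enc = enc, fc_mu = fc_mu, fc_logvar = fc_logvar, dec_fc = dec_fc,
       dec = dec, feat_dim = d)
}

build_ae_layers <- function(cfg) {
  d <- c(cfg$input_size, cfg$input_size, cfg$input_channels)
  enc <- list()
  for (i in 1:4) {
    cv <- layer_conv(d, cfg$conv_channels[i], kernel = cfg$kernel,
                     stride = cfg$stride, pad = cfg$padding, pad_mode = "zero")
    d <- cv$out_dim
    enc <- c(enc, list(cv, layer_bn(d), layer_lrelu(d, cfg$leaky_slope)))
  }
  bt <- layer_conv(d, cfg$bottleneck_channels, kernel = cfg$kernel,
                   stride = 1, pad = cfg$padding, pad_mode = "zero")
  d <- bt$out_dim
  enc <- c(enc, list(bt, layer_bn(d), layer_lrelu(d, cfg$leaky_slope)))
  bottleneck_dim <- d
  dec <- list()
  for (i in 4:1) {
    cv <- layer_conv(d, cfg$conv_channels[i], kernel = cfg$kernel,
                     stride = 1, pad = cfg$padding, pad_mode = "zero")
    d <- cv$out_dim
    dec <- c(dec, list(cv, layer_bn(d), layer_lrelu(d, cfg$leaky_slope)))
  }
  out_cv <- layer_conv(d, cfg$input_channels, kernel = cfg$kernel, stride = 1,
                       pad = cfg$padding, pad_mode = "zero")
  dec <- c(dec, list(out_cv, layer_sigmoid(out_cv$out_dim)))
  list(enc = enc, dec = dec, feat_dim = bottleneck_dim)
}

# ---- batch plumbing ---------------------------------------------------------

# Accepts: one H x W x C array, a list of patches / arrays, an N x H x W x C
# array, or an already-flat D x N matrix. Returns D x N.
as_model_batch <- function(model, x) {
  s <- model$config$input_size
  ch <- model$config$input_channels
  D <- s * s * ch
  if (is.matrix(x)) {
    check_that(nrow(x) == D, sprintf(
      "batch rows (%d) do not match expected %dx%dx%d input", nrow(x), s, s, ch))
    return(x)
  }
  if (is.list(x)) {
    arrs <- lapply(x, function(p) if (inherits(p, "berry_patch")) p$pixels else p)
    for (a in arrs)
      check_that(length(dim(a)) == 3 && dim(a)[1] == s && dim(a)[2] == s,
                 sprintf("patch spatial size must be %dx%d", s, s))
    return(batch_from_arrays(arrs))
  }
  if (length(dim(x)) == 3) {
    check_that(dim(x)[1] == s && dim(x)[2] == s,
               sprintf("input spatial size must be %dx%d, got %dx%d",
                       s, s, dim(x)[1], dim(x)[2]))
    return(matrix(as.numeric(x), ncol = 1))
  }
  if (length(dim(x)) == 4) {
    check_that(dim(x)[2] == s && dim(x)[3] == s,
               sprintf("input spatial size must be %dx%d", s, s))
    n <- dim(x)[1]
    return(vapply(seq_len(n), function(i) as.numeric(x[i, , , ]), numeric(D)))
  }
  abort_validation("unsupported batch input")
}

# ---- encode / reparameterize / decode --------------------------------------

#' Encode patches to latent Gaussian parameters
#'
#' @param model a `berry_model` of kind `fpl_vae`.
#' @param x input batch (array, list of patches, or D x N matrix; values in
#'   \[0,1\]).
#' @param training logical; TRUE uses batch statistics in batch norm (training
#'   pass), FALSE the running statistics (deterministic eval pass).
#' @return a [latent_distribution()] whose `mean` / `log_variance` are
#'   latent_dim x N matrices (one sample per column).
#' @export
encode <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "fpl_vae"))
  xb <- as_model_batch(model, x)
  ef <- seq_forward(model$enc, xb, training = training)
  mu <- layer_forward(model$fc_mu, ef$out)$out
  lv <- layer_forward(model$fc_logvar, ef$out)$out
  latent_distribution(mu, lv)
}

#' Reparameterization trick
#'
#' Draws latent vectors as `z = mu + exp(log_variance / 2) * eps` with
#' externally supplied standard-normal noise, keeping sampling
#' differentiable.
#'
#' @param dist a [latent_distribution()].
#' @param eps noise with the same shape as `dist$mean`; 0 gives `z = mu`.
#' @return latent vector(s), same shape as `dist$mean`.
#' @export
reparameterize <- function(dist, eps) {
  stopifnot(inherits(dist, "latent_distribution"))
  if (length(eps) == 1) {
    eps <- if (is.matrix(dist$mean))
      matrix(eps, nrow(dist$mean), ncol(dist$mean))
    else rep(eps, length(dist$mean))
  }
  check_that(length(eps) == length(dist$mean),
             "eps must have the same length as the latent mean")
  dist$mean + exp(0.5 * dist$log_variance) * eps
}

#' Decode latent vectors to reconstructed patches
#'
#' @param model a `berry_model` of kind `fpl_vae`.
#' @param z latent vector (length latent_dim) or latent_dim x N matrix.
#' @param training batch-norm mode, as in [encode()].
#' @param as_array return H x W x C arrays (single input) / list of arrays.
#' @return reconstruction(s) with values in \[0,1\].
#' @export
decode <- function(model, z, training = FALSE, as_array = TRUE) {
  stopifnot(inherits(model, "fpl_vae"))
  single <- !is.matrix(z)
  if (single) z <- matrix(z, ncol = 1)
  check_that(nrow(z) == model$config$latent_dim,
             sprintf("latent length must be %d, got %d",
                     model$config$latent_dim, nrow(z)))
  h <- layer_forward(model$dec_fc, z)$out
  df <- seq_forward(model$dec, h, training = training)
  out <- df$out
  if (!as_array) return(out)
  s <- model$config$input_size; ch <- model$config$input_channels
  arrs <- lapply(seq_len(ncol(out)), function(i) array(out[, i], c(s, s, ch)))
  if (single) arrs[[1]] else arrs
}

#' Full forward pass of the variational autoencoder
#'
#' `reconstruction = decode(reparameterize(encode(x), eps))`; both the
#' reconstruction and the latent distribution are returned for loss
#' computation.
#'
#' @param model `fpl_vae` model.
#' @param x input batch.
#' @param eps noise: a matrix matching the latent shape, a single number
#'   (recycled; 0 gives the deterministic pass), or `NULL` to sample N(0,1).
#' @param training batch-norm mode.
#' @return list with `reconstruction` (D x N matrix), `dist`
#'   (latent_distribution), `z`, and `eps` actually used.
#' @export
forward_vae <- function(model, x, eps = 0, training = FALSE) {
  dist <- encode(model, x, training = training)
  d <- dim(dist$mean)
  if (is.null(eps)) eps <- matrix(rnorm(prod(d)), d[1], d[2])
  if (length(eps) == 1) eps <- matrix(eps, d[1], d[2])
  z <- reparameterize(dist, eps)
  rec <- decode(model, z, training = training, as_array = FALSE)
  list(reconstruction = rec, dist = dist, z = z, eps = eps)
}

#' Forward pass of the baseline autoencoder
#'
#' Deterministic bottleneck: no latent distribution, no KL term.
#'
#' @param model `berry_model` of kind `fpl_ae` or `ssim_ae`.
#' @param x input batch.
#' @param training batch-norm mode.
#' @return D x N matrix of reconstructions in \[0,1\].
#' @export
forward_ae <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "fpl_ae") || inherits(model, "ssim_ae"))
  xb <- as_model_batch(model, x)
  ef <- seq_forward(model$enc, xb, training = training)
  seq_forward(model$dec, ef$out, training = training)$out
}

#' Reconstruct patches with a trained model
#'
#' The deterministic scoring pass: eval-mode batch norm and, for the VAE,
#' `eps = 0` so the latent vector is the posterior mean.
#'
#' @param model any `berry_model`.
#' @param x input batch (see [encode()] for accepted forms).
#' @return list of H x W x C reconstruction arrays (or a single array when a
#'   single array was supplied).
#' @export
reconstruct <- function(model, x) {
  single <- length(dim(x)) == 3
  xb <- as_model_batch(model, x)
  out <- if (inherits(model, "fpl_vae"))
    forward_vae(model, xb, eps = 0, training = FALSE)$reconstruction
  else forward_ae(model, xb, training = FALSE)
  s <- model$config$input_size; ch <- model$config$input_channels
  arrs <- lapply(seq_len(ncol(out)), function(i) array(out[, i], c(s, s, ch)))
  if (single) arrs[[1]] else arrs
}

# ---- bookkeeping ------------------------------------------------------------

model_params <- function(model) {
  p <- layers_params(model$enc, "enc")
  if (inherits(model, "fpl_vae")) {
    p <- c(p, layers_params(list(model$fc_mu), "fc_mu"),
           layers_params(list(model$fc_logvar), "fc_logvar"),
           layers_params(list(model$dec_fc), "dec_fc"))
  }
  c(p, layers_params(model$dec, "dec"))
}

model_set_params <- function(model, params) {
  model$enc <- layers_set_params(model$enc, params, "enc")
  if (inherits(model, "fpl_vae")) {
    model$fc_mu <- layers_set_params(list(model$fc_mu), params, "fc_mu")[[1]]
    model$fc_logvar <- layers_set_params(list(model$fc_logvar), params, "fc_logvar")[[1]]
    model$dec_fc <- layers_set_params(list(model$dec_fc), params, "dec_fc")[[1]]
  }
  model$dec <- layers_set_params(model$dec, params, "dec")
  model
}

#' Total number of trainable parameters in a model
#' @param model a `berry_model`.
#' @return integer parameter count.
#' @export
model_param_count <- function(model)
  sum(vapply(model_params(model), length, integer(1)))

#' Layer table of a model
#'
#' @param model a `berry_model`.
#' @return data.frame with one row per layer: part, index, type, output shape
#'   and parameter count.
#' @export
model_describe <- function(model) {
  row <- function(part, i, ly) data.frame(
    part = part, index = i, type = ly$type,
    out_shape = paste(ly$out_dim, collapse = "x"),
    params = length(ly[["W"]]) + length(ly[["b"]]) +
      length(ly[["gamma"]]) + length(ly[["beta"]]),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, c(
    lapply(seq_along(model$enc), function(i) row("encoder", i, model$enc[[i]])),
    if (inherits(model, "fpl_vae")) list(
      row("latent", 1, model$fc_mu), row("latent", 2, model$fc_logvar),
      row("latent", 3, model$dec_fc)),
    lapply(seq_along(model$dec), function(i) row("decoder", i, model$dec[[i]]))))
  rownames(out) <- NULL
  out
}

#' Save / load a model checkpoint
#'
#' Single-file binary checkpoint embedding the config, weights, batch-norm
#' running statistics and the initialisation seed.
#'
#' @param model a `berry_model`.
#' @param path file path for the checkpoint.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  check_that(file.exists(path),
             paste("no model checkpoint at", path),
             class = "berryvae_state_error")
  m <- readRDS(path)
  check_that(inherits(m, "berry_model"), "file is not a model checkpoint",
             class = "berryvae_state_error")
  m
}

#' @export
print.berry_model <- function(x, ...) {
  cat(sprintf("<berry_model %s | %d params | %s>\n", x$kind,
              model_param_count(x),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}
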