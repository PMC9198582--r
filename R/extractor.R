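# Frozen feature extractors for the feature perceptual loss.
#
# Three modes:
#   * deterministic_random — a seeded random CNN with a VGG-like topology
#     (3x3 conv + ReLU taps, 2x2 average pooling between stages). Fully
#     self-contained; the default for tests and reproducible runs. Random
#     convolutional features preserve differences between images well enough
#     to drive the perceptual loss, and are bit-reproducible from the seed.
#   * pretrained_vgg19 — the 19-layer VGGNet convolutional stack, loaded from
#     a user-supplied weights file (an RDS list; see details). The production
#     choice when trained weights are available locally.
#   * identity — taps the raw input itself; useful as a stub in unit tests
#     (the perceptual loss then reduces to a normalised pixel loss).

#' Specify a feature extractor for the perceptual loss
#'
#' @param mode one of `"deterministic_random"`, `"pretrained_vgg19"`,
#'   `"identity"`.
#' @param layer_names ordered character vector of tap points. For the random
#'   mode these are `"relu1" ... "relu<n_stages>"`; for VGG19 they are names
#'   like `"relu1_1"`, `"relu2_1"`, `"relu3_1"`.
#' @param channels integer vector of per-stage widths (random mode only).
#' @param seed integer seed for the random mode's frozen weights.
#' @param weights_path path to an RDS file holding VGG19 conv weights
#'   (`pretrained_vgg19` mode). The file must contain a named list with
#'   elements `conv<b>_<i>` each a list `(W = out x in x kh x kw array,
#'   b = vector)`.
#' @param input_size spatial size of inputs fed to the extractor.
#' @return an object of class `feature_extractor_spec`.
#' @export
feature_extractor_spec <- function(mode = c("deterministic_random",
                                            "pretrained_vgg19", "identity"),
                                   layer_names = NULL,
                                   channels = c(16L, 32L, 64L),
                                   seed = 7L,
                                   weights_path = NULL,
                                   input_size = 64L) {
  mode <- match.arg(mode)
  if (is.null(layer_names)) {
    # random mode taps the pre-activation conv maps: with frozen random
    # weights, linear taps keep the loss well conditioned (ReLU taps discard
    # half the gradient signal and measurably stall training); the VGG path
    # keeps the conventional post-activation taps
    layer_names <- switch(mode,
      deterministic_random = paste0("conv", seq_along(channels)),
      pretrained_vgg19 = c("relu1_1", "relu2_1", "relu3_1"),
      identity = "input")
  }
  check_that(length(layer_names) > 0, "layer_names must be non-empty")
  structure(list(mode = mode, layer_names = layer_names,
                 channels = as.integer(channels), seed = as.integer(seed),
                 weights_path = weights_path,
                 input_size = as.integer(input_size)),
            class = "feature_extractor_spec")
}

#' Build the frozen feature extractor described by a spec
#'
#' @param spec a [feature_extractor_spec()].
#' @param input_channels number of image channels (3 for RGB patches).
#' @return an object of class `feature_extractor` with frozen weights and a
#'   `fingerprint` checksum of those weights.
#' @export
build_extractor <- function(spec, input_channels = 3L) {
  stopifnot(inherits(spec, "feature_extractor_spec"))
  dim0 <- c(spec$input_size, spec$input_size, input_channels)
  if (spec$mode == "identity") {
    ext <- list(spec = spec, layers = list(), taps = integer(0),
                tap_names = "input", tap_input = TRUE, in_dim = dim0,
                fingerprint = "fp-identity")
    class(ext) <- "feature_extractor"
    return(ext)
  }
  if (spec$mode == "deterministic_random") {
    layers <- list()
    names_out <- character(0)
    d <- dim0
    with_seed(spec$seed, {
      for (s in seq_along(spec$channels)) {
        cv <- layer_conv(d, spec$channels[s], kernel = 3, stride = 1, pad = 1,
                         pad_mode = "zero")
        layers <- c(layers, list(cv)); names_out <- c(names_out, paste0("conv", s))
        d <- cv$out_dim
        layers <- c(layers, list(layer_relu(d)))
        names_out <- c(names_out, paste0("relu", s))
        if (s < length(spec$channels)) {
          pl <- layer_avgpool2(d)
          layers <- c(layers, list(pl)); names_out <- c(names_out, paste0("pool", s))
          d <- pl$out_dim
        }
      }
    })
  } else {  # pretrained_vgg19
    check_that(!is.null(spec$weights_path) && file.exists(spec$weights_path),
      paste("pretrained_vgg19 mode needs a local weights file (RDS);",
            "none found at the configured weights_path.",
            "Use mode = 'deterministic_random' for a self-contained run."),
      class = "berryvae_config_error")
    wts <- readRDS(spec$weights_path)
    blocks <- c(2L, 2L, 4L, 4L, 4L)
    widths <- c(64L, 128L, 256L, 512L, 512L)
    layers <- list(); names_out <- character(0)
    d <- dim0
    for (b in seq_along(blocks)) {
      for (i in seq_len(blocks[b])) {
        nm <- sprintf("conv%d_%d", b, i)
        check_that(nm %in% names(wts), paste("weights file missing", nm),
                   class = "berryvae_config_error")
        cv <- layer_conv(d, widths[b], kernel = 3, stride = 1, pad = 1,
                         pad_mode = "zero")
        cv$W <- vgg_weight_matrix(wts[[nm]]$W)
        cv$b <- as.numeric(wts[[nm]]$b)
        layers <- c(layers, list(cv)); names_out <- c(names_out, nm)
        d <- cv$out_dim
        layers <- c(layers, list(layer_relu(d)))
        names_out <- c(names_out, sprintf("relu%d_%d", b, i))
      }
      pl <- layer_maxpool2(d)
      layers <- c(layers, list(pl)); names_out <- c(names_out, sprintf("pool%d", b))
      d <- pl$out_dim
      # stop once every requested tap has been placed
      if (all(spec$layer_names %in% names_out)) break
    }
  }
  missing <- setdiff(spec$layer_names, names_out)
  check_that(length(missing) == 0,
             paste("unknown extractor layer name(s):",
                   paste(missing, collapse = ", ")),
             class = "berryvae_config_error")
  taps <- match(spec$layer_names, names_out)
  keep <- seq_len(max(taps))          # drop layers past the deepest tap
  params <- lapply(layers[keep], function(l) l$W %||% NULL)
  ext <- list(spec = spec, layers = layers[keep], layer_names = names_out[keep],
              taps = taps, tap_names = spec$layer_names, tap_input = FALSE,
              in_dim = dim0,
              fingerprint = weights_fingerprint(Filter(Negate(is.null), params)))
  class(ext) <- "feature_extractor"
  ext
}

# reorder a (out, in, kh, kw) weight array into this package's outC x K layout
vgg_weight_matrix <- function(Warr) {
  oc <- dim(Warr)[1]; ic <- dim(Warr)[2]; kh <- dim(Warr)[3]; kw <- dim(Warr)[4]
  Wm <- matrix(0, oc, kh * kw * ic)
  for (c in seq_len(ic)) for (dw in seq_len(kw)) for (dh in seq_len(kh))
    Wm[, (dh - 1) + kh * (dw - 1) + kh * kw * (c - 1) + 1] <- Warr[, c, dh, dw]
  Wm
}

# Forward pass collecting tapped feature maps.
# Returns list(features = list of matrices (dim attr per tap), dims = list of
# c(H, W, C), caches = layer caches when keep_cache).
extractor_forward <- function(ext, x, keep_cache = FALSE) {
  if (ext$tap_input) {
    return(list(features = list(x), dims = list(ext$in_dim), caches = NULL))
  }
  feats <- vector("list", length(ext$taps))
  dims <- vector("list", length(ext$taps))
  caches <- if (keep_cache) vector("list", length(ext$layers)) else NULL
  cur <- x
  for (i in seq_along(ext$layers)) {
    r <- layer_forward(ext$layers[[i]], cur, training = FALSE)
    cur <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    hit <- which(ext$taps == i)
    for (t in hit) {
      feats[[t]] <- cur
      dims[[t]] <- ext$layers[[i]]$out_dim
    }
  }
  list(features = feats, dims = dims, caches = caches)
}

# Backpropagate tap-level gradients (same shapes as the features) to the
# extractor input. Weights are frozen, so no parameter gradients.
extractor_backward <- function(ext, caches, tap_grads) {
  if (ext$tap_input) return(tap_grads[[1]])
  g <- NULL
  for (i in rev(seq_along(ext$layers))) {
    hit <- which(ext$taps == i)
    for (t in hit) g <- if (is.null(g)) tap_grads[[t]] else g + tap_grads[[t]]
    if (!is.null(g))
      g <- layer_backward(ext$layers[[i]], caches[[i]], g,
                          need_param_grads = FALSE)$gx
  }
  g
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor mode=%s taps=%s fingerprint=%s>\n",
              x$spec$mode, paste(x$tap_names, collapse = ","), x$fingerprint))
  invisible(x)
}
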