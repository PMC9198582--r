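# Minimal layer framework: each layer is a list with a `type`, its parameters,
# and its input geometry. Batches are D x N matrices (see image_ops.R for the
# layout). Forward passes return caches sufficient for exact backward passes;
# batch-norm layers additionally carry running statistics updated in training
# mode and used in eval mode.

layer_conv <- function(in_dim, out_channels, kernel, stride, pad,
                       pad_mode = c("zero", "replicate")) {
  pad_mode <- match.arg(pad_mode)
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]
  K <- kernel * kernel * C
  outH <- (H + 2 * pad - kernel) %/% stride + 1
  outW <- (W + 2 * pad - kernel) %/% stride + 1
  # He-style fan-in init; caller controls the RNG stream
  Wm <- matrix(rnorm(out_channels * K, 0, sqrt(2 / K)), out_channels, K)
  list(type = "conv", W = Wm, b = numeric(out_channels),
       kernel = kernel, stride = stride, pad = pad,
       pad_mode_int = if (pad_mode == "replicate") 1L else 0L,
       in_dim = in_dim, out_dim = c(outH, outW, out_channels))
}

layer_bn <- function(dim, momentum = 0.1, eps = 1e-5) {
  C <- dim[3]
  list(type = "bn", gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C),
       momentum = momentum, eps = eps, in_dim = dim, out_dim = dim)
}

layer_lrelu <- function(dim, slope = 0.2)
  list(type = "lrelu", slope = slope, in_dim = dim, out_dim = dim)

layer_relu <- function(dim) list(type = "relu", in_dim = dim, out_dim = dim)

layer_sigmoid <- function(dim) list(type = "sigmoid", in_dim = dim, out_dim = dim)

layer_upsample2 <- function(dim) {
  H <- dim[1]; W <- dim[2]; C <- dim[3]
  oH <- 2L * H; oW <- 2L * W
  # output flat index -> input flat index (nearest neighbour)
  h <- rep(seq_len(oH), times = oW * C)
  w <- rep(rep(seq_len(oW), each = oH), times = C)
  c <- rep(seq_len(C), each = oH * oW)
  idx <- ((h - 1) %/% 2 + 1) + H * ((w - 1) %/% 2) + H * W * (c - 1)
  list(type = "upsample2", idx = idx, in_dim = dim, out_dim = c(oH, oW, C))
}

layer_avgpool2 <- function(dim)
  list(type = "avgpool2", in_dim = dim,
       out_dim = c(dim[1] %/% 2L, dim[2] %/% 2L, dim[3]))

layer_maxpool2 <- function(dim) {
  H <- dim[1]; W <- dim[2]; C <- dim[3]
  oH <- H %/% 2L; oW <- W %/% 2L
  oh <- rep(seq_len(oH), times = oW * C)
  ow <- rep(rep(seq_len(oW), each = oH), times = C)
  cc <- rep(seq_len(C), each = oH * oW)
  base <- (2 * oh - 1) + H * (2 * ow - 2) + H * W * (cc - 1)
  list(type = "maxpool2",
       idx = cbind(base, base + 1L, base + H, base + H + 1L),
       in_dim = dim, out_dim = c(oH, oW, C))
}

layer_fc <- function(n_in, n_out) {
  list(type = "fc", W = matrix(rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out), in_dim = n_in, out_dim = n_out)
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      d <- layer$in_dim
      out <- conv2d_fwd_cpp(x, layer$W, layer$b, d[1], d[2], d[3],
                            layer$kernel, layer$kernel, layer$stride,
                            layer$pad, layer$pad_mode_int)
      list(out = out, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- layer$in_dim
      C <- d[3]; hw <- d[1] * d[2]
      if (training) {
        st <- bn_stats_cpp(x, hw, C)
        use_mu <- as.numeric(st$mean); use_v <- as.numeric(st$var)
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean +
          layer$momentum * use_mu
        layer$run_var <- (1 - layer$momentum) * layer$run_var +
          layer$momentum * use_v
      } else {
        use_mu <- layer$run_mean; use_v <- layer$run_var
      }
      inv_sd <- 1 / sqrt(use_v + layer$eps)
      out <- bn_apply_cpp(x, hw, C, use_mu, inv_sd, layer$gamma, layer$beta)
      list(out = out,
           cache = list(x = x, mu = use_mu, inv_sd = inv_sd, batch = training),
           layer = layer)
    },
    lrelu = {
      neg <- x < 0
      out <- x
      out[neg] <- layer$slope * x[neg]
      list(out = out, cache = list(neg = neg), layer = layer)
    },
    relu = {
      neg <- x < 0
      out <- x
      out[neg] <- 0
      list(out = out, cache = list(neg = neg), layer = layer)
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      list(out = out, cache = list(out = out), layer = layer)
    },
    upsample2 = {
      out <- x[layer$idx, , drop = FALSE]
      list(out = out, cache = NULL, layer = layer)
    },
    avgpool2 = {
      d <- layer$in_dim
      out <- avgpool2_fwd_cpp(x, d[1], d[2], d[3])
      list(out = out, cache = NULL, layer = layer)
    },
    maxpool2 = {
      x1 <- x[layer$idx[, 1], , drop = FALSE]
      x2 <- x[layer$idx[, 2], , drop = FALSE]
      x3 <- x[layer$idx[, 3], , drop = FALSE]
      x4 <- x[layer$idx[, 4], , drop = FALSE]
      out <- pmax(x1, x2, x3, x4)
      am <- matrix(4L, nrow(out), ncol(out))
      am[x3 == out] <- 3L   # later assignments override: first index wins ties
      am[x2 == out] <- 2L
      am[x1 == out] <- 1L
      gi <- matrix(layer$idx[cbind(rep(seq_len(nrow(am)), ncol(am)),
                                   as.integer(am))],
                   nrow(am), ncol(am))
      list(out = out, cache = list(gi = gi), layer = layer)
    },
    fc = {
      out <- layer$W %*% x + layer$b
      list(out = out, cache = list(x = x), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, gout, need_param_grads = TRUE) {
  switch(layer$type,
    conv = {
      d <- layer$in_dim
      r <- conv2d_bwd_cpp(gout, cache$x, layer$W, d[1], d[2], d[3],
                          layer$kernel, layer$kernel, layer$stride,
                          layer$pad, layer$pad_mode_int, need_param_grads)
      list(gx = r$gx,
           grads = if (need_param_grads) list(W = r$gW, b = as.numeric(r$gb)) else NULL)
    },
    bn = {
      d <- layer$in_dim
      C <- d[3]; hw <- d[1] * d[2]
      r <- bn_bwd_cpp(gout, cache$x, hw, C, cache$mu, cache$inv_sd,
                      layer$gamma, cache$batch)
      list(gx = r$gx,
           grads = if (need_param_grads)
             list(gamma = as.numeric(r$ggamma), beta = as.numeric(r$gbeta))
           else NULL)
    },
    lrelu = {
      gx <- gout
      gx[cache$neg] <- layer$slope * gout[cache$neg]
      list(gx = gx, grads = NULL)
    },
    relu = {
      gx <- gout
      gx[cache$neg] <- 0
      list(gx = gx, grads = NULL)
    },
    sigmoid = {
      list(gx = gout * cache$out * (1 - cache$out), grads = NULL)
    },
    upsample2 = {
      gx <- rowsum(gout, layer$idx)
      list(gx = gx, grads = NULL)
    },
    avgpool2 = {
      d <- layer$in_dim
      list(gx = avgpool2_bwd_cpp(gout, d[1], d[2], d[3]), grads = NULL)
    },
    maxpool2 = {
      d <- layer$in_dim
      D <- prod(d); N <- ncol(gout)
      gx <- matrix(0, D, N)
      flat <- as.vector(cache$gi) + rep((seq_len(N) - 1L) * D, each = nrow(gout))
      gx[flat] <- as.vector(gout)
      list(gx = gx, grads = NULL)
    },
    fc = {
      list(gx = crossprod(layer$W, gout),
           grads = if (need_param_grads)
             list(W = tcrossprod(gout, cache$x), b = rowSums(gout)) else NULL)
    },
    stop("unknown layer type: ", layer$type)
  )
}

seq_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, gout, need_param_grads = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], gout, need_param_grads)
    gout <- r$gx
    grads[i] <- list(r$grads)   # keep NULLs as placeholders
  }
  list(gx = gout, grads = grads)
}

# ---- parameter bookkeeping (flat named lists for the optimizer) -------------

.param_fields <- c(conv = "W,b", fc = "W,b", bn = "gamma,beta")

layers_params <- function(layers, prefix) {
  out <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    f <- .param_fields[ly$type]
    if (is.na(f)) next
    for (nm in strsplit(f, ",")[[1]])
      out[[paste(prefix, i, nm, sep = ".")]] <- ly[[nm]]
  }
  out
}

layers_set_params <- function(layers, params, prefix) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    f <- .param_fields[ly$type]
    if (is.na(f)) next
    for (nm in strsplit(f, ",")[[1]]) {
      key <- paste(prefix, i, nm, sep = ".")
      if (!is.null(params[[key]])) layers[[i]][[nm]] <- params[[key]]
    }
  }
  layers
}

layers_grads_named <- function(layers, grads, prefix) {
  out <- list()
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]]))
      out[[paste(prefix, i, nm, sep = ".")]] <- grads[[i]][[nm]]
  }
  out
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params)
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
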