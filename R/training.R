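# One-class training: the models see healthy-berry patches only. The trainer
# minimises
#   FPL-VAE : alpha * KL + lambda * FPL
#   FPL-AE  : lambda * FPL
#   SSIM-AE : 1 - SSIM
# with Adam, early stopping on the validation total loss, and full RNG
# seeding for reproducible runs.

#' Training configuration
#'
#' @param batch_size training batch size.
#' @param val_batch_size validation batch size.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"`.
#' @param max_epochs maximum number of epochs.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param early_stop_min_delta minimum decrease of the validation total loss
#'   that counts as an improvement.
#' @param val_fraction fraction of healthy patches held out for validation
#'   (used by [split_healthy()]).
#' @param seed integer seed driving shuffling, noise and initialisation.
#' @param alpha,lambda_ weights of the KL and reconstruction terms. The
#'   default `alpha = NULL` resolves at training time to `0.01 / latent_dim`,
#'   which reproduces the reconstruction-dominant weighting of the classic
#'   feature-perceptual VAE design once the perceptual loss is normalised
#'   per feature element; heavier KL weights measurably silence the latent
#'   code (the decoder degenerates to an average image).
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, val_batch_size = 16L,
                         learning_rate = 5e-4, optimizer = "adam",
                         max_epochs = 200L, early_stop_patience = 10L,
                         early_stop_min_delta = 1e-4, val_fraction = 0.2,
                         seed = 1L, alpha = NULL, lambda_ = 1) {
  check_that(batch_size >= 1, "batch_size must be >= 1")
  check_that(val_fraction > 0 && val_fraction < 1,
             "val_fraction must be in (0, 1)")
  check_that(early_stop_patience >= 1, "early_stop_patience must be >= 1")
  check_that(identical(optimizer, "adam"), "only the adam optimizer is supported",
             class = "berryvae_config_error")
  check_that(is.null(alpha) || alpha >= 0, "alpha must be >= 0 (or NULL for auto)")
  check_that(lambda_ >= 0, "lambda_ must be >= 0")
  structure(list(batch_size = as.integer(batch_size),
                 val_batch_size = as.integer(val_batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_delta = early_stop_min_delta,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 alpha = alpha, lambda_ = lambda_),
            class = "train_config")
}

#' Split healthy patches into training and validation sets
#'
#' The trainer's one-class premise is enforced here: any patch labelled
#' anomalous is a contract violation. The split is stratified by stage tag
#' and deterministic under the seed.
#'
#' @param patches a `patch_set` or list of `berry_patch` objects, all labelled
#'   healthy (or unlabeled).
#' @param val_fraction fraction assigned to the validation set.
#' @param seed integer seed.
#' @return list with `train` and `val` lists of patches (disjoint,
#'   exhaustive).
#' @export
split_healthy <- function(patches, val_fraction = 0.2, seed = 1L) {
  pl <- as_patch_list(patches)
  labels <- vapply(pl, function(p) p$label, character(1))
  check_that(!any(labels == "anomalous"),
             "one-class training: input contains anomalous patches",
             class = "berryvae_contract_error")
  check_that(val_fraction > 0 && val_fraction < 1,
             "val_fraction must be in (0, 1)")
  stages <- vapply(pl, function(p) p$stage_tag, character(1))
  val_idx <- integer(0)
  with_seed(seed, {
    for (st in unique(stages)) {
      idx <- which(stages == st)
      n_val <- round(length(idx) * val_fraction)
      if (n_val > 0) val_idx <- c(val_idx, sample(idx, n_val))
    }
  })
  list(train = pl[setdiff(seq_along(pl), val_idx)], val = pl[sort(val_idx)])
}

# ---- loss + gradient of one batch ------------------------------------------

# Returns list(loss = list(total, rec, kl), grads = named list) and the model
# with updated batch-norm running stats.
train_step <- function(model, xb, extractor, cfg, compute_grads = TRUE,
                       training = TRUE, eps = NULL) {
  N <- ncol(xb)
  if (inherits(model, "fpl_vae")) {
    ef <- seq_forward(model$enc, xb, training = training)
    model$enc <- ef$layers
    rmu <- layer_forward(model$fc_mu, ef$out)
    rlv <- layer_forward(model$fc_logvar, ef$out)
    mu <- rmu$out; lv <- rlv$out
    if (is.null(eps)) eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
    z <- mu + exp(0.5 * lv) * eps
    rfc <- layer_forward(model$dec_fc, z)
    df <- seq_forward(model$dec, rfc$out, training = training)
    model$dec <- df$layers
    xhat <- df$out
    fx <- extractor_forward(extractor, xb, keep_cache = FALSE)
    fy <- extractor_forward(extractor, xhat, keep_cache = compute_grads)
    L <- length(fx$features)
    rec <- 0
    tap_grads <- vector("list", L)
    for (l in seq_len(L)) {
      dml <- fx$dims[[l]]
      norm <- 2 * prod(dml)
      diff <- fy$features[[l]] - fx$features[[l]]
      rec <- rec + sum(diff^2) / norm / N
      if (compute_grads)
        tap_grads[[l]] <- (cfg$lambda_ / (prod(dml) * N)) * diff
    }
    kl <- mean(0.5 * colSums(mu^2 + exp(lv) - 1 - lv))
    loss <- list(total = cfg$alpha * kl + cfg$lambda_ * rec, rec = rec, kl = kl)
    if (!compute_grads)
      return(list(loss = loss, grads = NULL, model = model))
    g_xhat <- extractor_backward(extractor, fy$caches, tap_grads)
    db <- seq_backward(model$dec, df$caches, g_xhat)
    gfc <- layer_backward(model$dec_fc, rfc$cache, db$gx)
    g_z <- gfc$gx
    g_mu <- g_z + (cfg$alpha / N) * mu
    g_lv <- g_z * eps * 0.5 * exp(0.5 * lv) + (cfg$alpha / N) * 0.5 * (exp(lv) - 1)
    bmu <- layer_backward(model$fc_mu, rmu$cache, g_mu)
    blv <- layer_backward(model$fc_logvar, rlv$cache, g_lv)
    g_feat <- bmu$gx + blv$gx
    eb <- seq_backward(model$enc, ef$caches, g_feat)
    grads <- c(layers_grads_named(model$enc, eb$grads, "enc"),
               layers_grads_named(list(model$fc_mu), list(bmu$grads), "fc_mu"),
               layers_grads_named(list(model$fc_logvar), list(blv$grads), "fc_logvar"),
               layers_grads_named(list(model$dec_fc), list(gfc$grads), "dec_fc"),
               layers_grads_named(model$dec, db$grads, "dec"))
    return(list(loss = loss, grads = grads, model = model))
  }

  # baseline autoencoders
  ef <- seq_forward(model$enc, xb, training = training)
  model$enc <- ef$layers
  df <- seq_forward(model$dec, ef$out, training = training)
  model$dec <- df$layers
  xhat <- df$out
  if (inherits(model, "fpl_ae")) {
    fx <- extractor_forward(extractor, xb, keep_cache = FALSE)
    fy <- extractor_forward(extractor, xhat, keep_cache = compute_grads)
    L <- length(fx$features)
    rec <- 0
    tap_grads <- vector("list", L)
    for (l in seq_len(L)) {
      dml <- fx$dims[[l]]
      diff <- fy$features[[l]] - fx$features[[l]]
      rec <- rec + sum(diff^2) / (2 * prod(dml)) / N
      if (compute_grads)
        tap_grads[[l]] <- (cfg$lambda_ / (prod(dml) * N)) * diff
    }
    loss <- list(total = cfg$lambda_ * rec, rec = rec, kl = 0)
    if (!compute_grads) return(list(loss = loss, grads = NULL, model = model))
    g_xhat <- extractor_backward(extractor, fy$caches, tap_grads)
  } else {  # ssim_ae
    s <- model$config$input_size; ch <- model$config$input_channels
    rec <- 0
    g_xhat <- matrix(0, nrow(xhat), N)
    for (n in seq_len(N)) {
      xa <- array(xb[, n], c(s, s, ch))
      ya <- array(xhat[, n], c(s, s, ch))
      if (compute_grads) {
        sw <- ssim_with_grad(xa, ya)
        rec <- rec + (1 - sw$value) / N
        g_xhat[, n] <- -as.numeric(sw$grad) / N
      } else {
        rec <- rec + (1 - ssim(xa, ya)) / N
      }
    }
    loss <- list(total = rec, rec = rec, kl = 0)
    if (!compute_grads) return(list(loss = loss, grads = NULL, model = model))
  }
  db <- seq_backward(model$dec, df$caches, g_xhat)
  eb <- seq_backward(model$enc, ef$caches, db$gx)
  grads <- c(layers_grads_named(model$enc, eb$grads, "enc"),
             layers_grads_named(model$dec, db$grads, "dec"))
  list(loss = loss, grads = grads, model = model)
}

batch_loss_eval <- function(model, patches, extractor, cfg, batch_size) {
  n <- length(patches)
  tot <- rec <- kl <- 0
  i <- 1
  while (i <= n) {
    j <- min(i + batch_size - 1, n)
    xb <- batch_from_arrays(lapply(patches[i:j], function(p) p$pixels))
    r <- train_step(model, xb, extractor, cfg, compute_grads = FALSE,
                    training = FALSE, eps = 0)
    w <- (j - i + 1) / n
    tot <- tot + r$loss$total * w
    rec <- rec + r$loss$rec * w
    kl <- kl + r$loss$kl * w
    i <- j + 1
  }
  list(total = tot, rec = rec, kl = kl)
}

#' Train an anomaly-detection model on healthy patches
#'
#' Minimises the model's objective with Adam, evaluating the validation loss
#' each epoch (deterministic pass: eval-mode batch norm, zero latent noise)
#' and stopping early when it fails to improve by `early_stop_min_delta` for
#' `early_stop_patience` consecutive epochs. The best-epoch weights are
#' restored in the returned model.
#'
#' @param model an untrained or pre-trained `berry_model`.
#' @param train_set,val_set lists of healthy `berry_patch` objects (see
#'   [split_healthy()]).
#' @param cfg a [train_config()].
#' @param extractor a built extractor, an extractor spec, or `NULL` for the
#'   default deterministic-random spec (ignored by `ssim_ae`).
#' @param checkpoint_path optional path; when given, the best model is saved
#'   there.
#' @param verbose print one line per epoch.
#' @return object of class `train_report`: `model`, `epochs_run`,
#'   `best_epoch`, `history` (data.frame of per-epoch losses),
#'   `stopped_early`, `checkpoint_path`, `config_snapshot`,
#'   `extractor_fingerprint`.
#' @export
train <- function(model, train_set, val_set, cfg = train_config(),
                  extractor = NULL, checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "berry_model"), inherits(cfg, "train_config"))
  train_set <- as_patch_list(train_set)
  val_set <- as_patch_list(val_set)
  check_that(length(train_set) > 0 && length(val_set) > 0,
             "train and validation sets must be non-empty")
  for (p in c(train_set, val_set))
    check_that(!identical(p$label, "anomalous"),
               "one-class training: input contains anomalous patches",
               class = "berryvae_contract_error")
  if (is.null(cfg$alpha))
    cfg$alpha <- if (inherits(model, "fpl_vae"))
      0.01 / model$config$latent_dim else 0
  needs_ext <- model$kind %in% c("fpl_vae", "fpl_ae")
  if (needs_ext) {
    if (is.null(extractor)) extractor <- feature_extractor_spec(
      input_size = model$config$input_size)
    if (inherits(extractor, "feature_extractor_spec"))
      extractor <- build_extractor(extractor, model$config$input_channels)
  } else extractor <- NULL

  params <- model_params(model)
  opt <- adam_init(params)
  history <- data.frame()
  best_val <- Inf
  best_epoch <- 0L
  best_params <- params
  best_bn <- NULL
  bad_epochs <- 0L
  stopped_early <- FALSE
  n <- length(train_set)

  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_tot <- ep_rec <- ep_kl <- 0
    i <- 1
    batch_id <- 0
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1, n)
      batch_id <- batch_id + 1
      xb <- batch_from_arrays(lapply(train_set[ord[i:j]], function(p) p$pixels))
      r <- train_step(model, xb, extractor, cfg, compute_grads = TRUE,
                      training = ncol(xb) > 1)
      if (!is.finite(r$loss$total))
        stop(sprintf("non-finite training loss at epoch %d, batch %d", epoch,
                     batch_id))
      model <- r$model
      params <- model_params(model)   # pick up running-stat updates? (weights unchanged)
      up <- adam_step(params, r$grads, opt, cfg$learning_rate)
      params <- up$params
      opt <- up$state
      model <- model_set_params(model, params)
      w <- (j - i + 1) / n
      ep_tot <- ep_tot + r$loss$total * w
      ep_rec <- ep_rec + r$loss$rec * w
      ep_kl <- ep_kl + r$loss$kl * w
      i <- j + 1
    }
    vl <- batch_loss_eval(model, val_set, extractor, cfg, cfg$val_batch_size)
    if (!is.finite(vl$total))
      stop(sprintf("non-finite validation loss at epoch %d", epoch))
    history <- rbind(history, data.frame(
      epoch = epoch, train_total = ep_tot, train_rec = ep_rec,
      train_kl = ep_kl, val_total = vl$total, val_rec = vl$rec,
      val_kl = vl$kl))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, ep_tot, vl$total))
    if (vl$total < best_val - cfg$early_stop_min_delta) {
      best_val <- vl$total
      best_epoch <- epoch
      best_params <- params
      best_bn <- snapshot_bn(model)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$early_stop_patience) {
        stopped_early <- TRUE
        break
      }
    }
  }
  if (best_epoch == 0L) { best_epoch <- nrow(history); best_bn <- snapshot_bn(model) }
  model <- model_set_params(model, best_params)
  model <- restore_bn(model, best_bn)
  model$trained <- TRUE
  if (!is.null(checkpoint_path)) save_model(model, checkpoint_path)
  structure(list(model = model, epochs_run = nrow(history),
                 best_epoch = best_epoch, history = history,
                 stopped_early = stopped_early,
                 checkpoint_path = checkpoint_path, config_snapshot = cfg,
                 extractor_fingerprint =
                   if (!is.null(extractor)) extractor$fingerprint else NA_character_),
            class = "train_report")
}

snapshot_bn <- function(model) {
  grab <- function(layers) lapply(layers, function(l)
    if (l$type == "bn") list(m = l$run_mean, v = l$run_var) else NULL)
  list(enc = grab(model$enc), dec = grab(model$dec))
}

restore_bn <- function(model, snap) {
  if (is.null(snap)) return(model)
  put <- function(layers, s) {
    for (i in seq_along(layers)) if (!is.null(s[[i]])) {
      layers[[i]]$run_mean <- s[[i]]$m
      layers[[i]]$run_var <- s[[i]]$v
    }
    layers
  }
  model$enc <- put(model$enc, snap$enc)
  model$dec <- put(model$dec, snap$dec)
  model
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report %d epochs (best %d)%s | final val %.5f>\n",
              x$epochs_run, x$best_epoch,
              if (x$stopped_early) ", stopped early" else "",
              tail(x$history$val_total, 1)))
  invisible(x)
}
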