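# Trainer: one-class purity, splitting, early stopping, determinism,
# learning progress on a tiny problem.

test_that("split_healthy is stratified, exhaustive, and seed-deterministic", {
  pl <- tiny_patches(n = 100)
  sp <- split_healthy(pl, val_fraction = 0.2, seed = 3)
  expect_length(sp$val, 20)
  expect_length(sp$train, 80)
  ids <- function(x) vapply(x, function(p) p$patch_id, character(1))
  expect_length(intersect(ids(sp$train), ids(sp$val)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$val)), ids(pl))
  # stratification: both stages appear proportionally in the validation set
  st <- table(vapply(sp$val, function(p) p$stage_tag, character(1)))
  expect_true(all(abs(st - 10) <= 1))
  sp2 <- split_healthy(pl, val_fraction = 0.2, seed = 3)
  expect_identical(ids(sp$val), ids(sp2$val))
})

test_that("the trainer refuses anomalous patches (one-class premise)", {
  pl <- tiny_patches(n = 10)
  pl[[4]]$label <- "anomalous"
  expect_error(split_healthy(pl, 0.2, 1), "one-class")
  m <- build_model("fpl_vae", tiny_vae_config(), seed = 1)
  expect_error(train(m, pl, pl[1:2], train_config(max_epochs = 1)),
               "one-class")
})

test_that("early stopping triggers after patience epochs without improvement", {
  # learning rate 0 freezes the weights, so the validation loss is constant
  pl <- tiny_patches(n = 12)
  m <- build_model("fpl_ae", tiny_ae_config(), seed = 2)
  cfg <- train_config(batch_size = 6, learning_rate = 0, max_epochs = 10,
                      early_stop_patience = 1, seed = 1)
  rep <- train(m, pl[1:8], pl[9:12], cfg, extractor = tiny_extractor_spec())
  expect_true(rep$stopped_early)
  expect_equal(rep$epochs_run, 2)   # one improvement-free epoch after the first
  expect_true(all(is.finite(rep$history$train_total)))
  expect_equal(nrow(rep$history), rep$epochs_run)
  expect_lte(rep$best_epoch, rep$epochs_run)
})

test_that("training reduces the validation reconstruction loss", {
  set.seed(5)
  # structured 16x16 patches: blurred blobs, learnable by a tiny model
  pl <- lapply(1:40, function(i) {
    base <- berryvae:::blur_gaussian(matrix(runif(256), 16, 16), 2)
    px <- array(0, c(16, 16, 3))
    px[, , 1] <- base * 0.4; px[, , 2] <- base; px[, , 3] <- base * 0.6
    berry_patch(pmin(px, 1), c(0, 0), 16, sprintf("p%d", i), "healthy",
                c("early", "late")[i %% 2 + 1])
  })
  m <- build_model("fpl_vae", tiny_vae_config(latent_dim = 8), seed = 3)
  cfg <- train_config(batch_size = 8, learning_rate = 2e-3, max_epochs = 8,
                      alpha = 1 / 8, seed = 2)
  rep <- train(m, pl[1:32], pl[33:40], cfg, extractor = tiny_extractor_spec())
  expect_lt(tail(rep$history$val_rec, 1), rep$history$val_rec[1])
  expect_true(isTRUE(rep$model$trained))
})

test_that("identical data, config, and seeds give identical loss histories", {
  pl <- tiny_patches(n = 16)
  cfg <- train_config(batch_size = 8, max_epochs = 2, seed = 7)
  r1 <- train(build_model("fpl_ae", tiny_ae_config(), seed = 4),
              pl[1:12], pl[13:16], cfg, extractor = tiny_extractor_spec())
  r2 <- train(build_model("fpl_ae", tiny_ae_config(), seed = 4),
              pl[1:12], pl[13:16], cfg, extractor = tiny_extractor_spec())
  expect_identical(r1$history, r2$history)
})

test_that("checkpoints written by the trainer reproduce scores exactly", {
  dir <- withr::local_tempdir()
  pl <- tiny_patches(n = 16)
  cfg <- train_config(batch_size = 8, max_epochs = 2, seed = 7)
  path <- file.path(dir, "ck.rds")
  rep <- train(build_model("fpl_ae", tiny_ae_config(), seed = 4),
               pl[1:12], pl[13:16], cfg, extractor = tiny_extractor_spec(),
               checkpoint_path = path)
  s1 <- score_patches(rep$model, pl[13:16], "mse")
  s2 <- score_patches(load_model(path), pl[13:16], "mse")
  expect_identical(s1$score, s2$score)
})

test_that("scoring demands a trained model unless explicitly overridden", {
  m <- build_model("fpl_vae", tiny_vae_config(), seed = 1)
  pl <- tiny_patches(n = 3)
  expect_error(score_patches(m, pl), "untrained")
  s <- score_patches(m, pl, allow_untrained = TRUE)
  expect_equal(nrow(s), 3)
  expect_true(all(is.finite(s$score)))
  # identical calls give identical scores (eps = 0 pass)
  expect_identical(s$score, score_patches(m, pl, allow_untrained = TRUE)$score)
})
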