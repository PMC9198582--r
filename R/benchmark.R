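# Self-contained synthetic benchmark: the package's end-to-end demonstration
# at desk scale. Generates healthy training scenes and a balanced labelled
# evaluation set, trains the chosen model, scores, optimises the threshold,
# and compares against the untrained-model baseline.

#' Run the synthetic anomaly-detection benchmark
#'
#' One-call version of the full study at a configurable (default desk-scale)
#' size: train on healthy patches only, evaluate threshold accuracy on a
#' balanced healthy/anomalous patch set, stratified by growth stage.
#' All randomness derives from `seed`.
#'
#' @param seed integer master seed.
#' @param n_train_scenes healthy scenes for training (~9 patches each).
#' @param n_eval_scenes scenes per evaluation group (healthy / anomalous).
#' @param epochs training epochs.
#' @param batch_size,learning_rate optimiser settings for the scaled run.
#' @param model_config a [vae_config()]/[ae_config()]; default: the reduced-
#'   width VAE used for single-CPU runs.
#' @param kind model kind (see [build_model()]).
#' @param extractor_channels widths of the deterministic-random extractor.
#' @param extractor_taps tap layer names for the extractor.
#' @param metric scoring metric.
#' @param balance cap for the balanced evaluation set per class (`Inf` =
#'   use as many as available, balanced to the smaller class).
#' @return list with `model`, `report` (train_report), `records` (score
#'   data.frame), `threshold` (threshold_result), `untrained_threshold`,
#'   `stratified` (accuracy table), `medians`, `separation_p` (one-sided
#'   Wilcoxon rank-sum p-value for anomalous > healthy scores),
#'   `eval_scenes`, and `sizes`.
#' @export
synthetic_benchmark <- function(seed = 1L,
                                n_train_scenes = 100L,
                                n_eval_scenes = 20L,
                                epochs = 20L,
                                batch_size = 8L,
                                learning_rate = 2e-3,
                                model_config = vae_config(
                                  encoder_channels = c(8L, 16L, 32L, 64L),
                                  latent_dim = 64L,
                                  decoder_channels = c(32L, 16L, 8L, 8L)),
                                kind = "fpl_vae",
                                extractor_channels = c(16L, 32L, 64L),
                                extractor_taps = NULL,
                                metric = "mse",
                                balance = Inf) {
  tr_scenes <- generate_dataset(n_train_scenes, 0,
                                scene_spec(anomaly_fraction = 0),
                                seed = derive_seed(seed, 1))
  tr_patches <- unlist(lapply(tr_scenes,
                              function(s) scene_patches(s)$patches),
                       recursive = FALSE)
  ev_scenes <- generate_dataset(n_eval_scenes, n_eval_scenes, scene_spec(),
                                seed = derive_seed(seed, 2))
  ev_patches <- unlist(lapply(ev_scenes,
                              function(s) scene_patches(s)$patches),
                       recursive = FALSE)
  labs <- vapply(ev_patches, function(p) p$label, character(1))
  h_idx <- which(labs == "healthy")
  a_idx <- which(labs == "anomalous")
  nb <- min(length(h_idx), length(a_idx), balance)
  eval_set <- with_seed(derive_seed(seed, 3),
                        c(ev_patches[sample(h_idx, nb)],
                          ev_patches[sample(a_idx, nb)]))
  sp <- split_healthy(tr_patches, 0.2, seed = derive_seed(seed, 4))
  model <- build_model(kind, model_config, seed = derive_seed(seed, 5))
  ext <- if (kind %in% c("fpl_vae", "fpl_ae"))
    feature_extractor_spec(channels = extractor_channels, seed = 7L,
                           layer_names = extractor_taps,
                           input_size = model_config$input_size) else NULL
  cfg <- train_config(batch_size = batch_size, max_epochs = epochs,
                      learning_rate = learning_rate,
                      seed = derive_seed(seed, 6))
  report <- train(model, sp$train, sp$val, cfg, extractor = ext)
  records <- score_patches(report$model, eval_set, metric)
  thr <- optimize_threshold(records)
  untrained <- build_model(kind, model_config, seed = derive_seed(seed, 5))
  rec0 <- score_patches(untrained, eval_set, metric, allow_untrained = TRUE)
  thr0 <- optimize_threshold(rec0)
  hs <- records$score[records$label == "healthy"]
  as_ <- records$score[records$label == "anomalous"]
  wt <- stats::wilcox.test(as_, hs, alternative = "greater", exact = FALSE)
  list(model = report$model, report = report, records = records,
       threshold = thr, untrained_threshold = thr0,
       stratified = evaluate_stratified(records, thr$threshold),
       medians = c(healthy = stats::median(hs),
                   anomalous = stats::median(as_)),
       separation_p = wt$p.value,
       eval_scenes = ev_scenes,
       sizes = c(n_train = length(sp$train), n_val = length(sp$val),
                 n_eval_healthy = nb, n_eval_anomalous = nb))
}

#' Heatmap localisation check against a permutation null
#'
#' Assembles full-image heatmaps for damaged scenes and asks whether the
#' hottest pixels (top decile within the covered area) overlap the ground
#' truth anomaly masks more often than randomly placed pixel sets of the
#' same size (permutation null, pooled across scenes).
#'
#' @param model trained `berry_model`.
#' @param scenes list of `labeled_scene` with non-empty anomaly masks.
#' @param metric heatmap pixel loss.
#' @param top_quantile quantile defining "hottest" (0.9 = top decile).
#' @param n_draws permutation draws.
#' @param seed RNG seed for the draws.
#' @return list with `precision` (observed), `null_mean`, `p_value`
#'   (one-sided, (1 + #null >= obs) / (1 + draws)), `n_scenes`, `n_top`.
#' @export
heatmap_localization_test <- function(model, scenes, metric = "mse",
                                      top_quantile = 0.9, n_draws = 1000L,
                                      seed = 1L) {
  vals <- c(); truth <- c()
  for (sc in scenes) {
    check_that(sum(sc$anomaly_mask) > 0,
               "heatmap localisation needs damaged scenes")
    hm <- model_heatmap(model, sc$image, sc$berry_mask, metric,
                        scene_id = sc$scene_id)
    keep <- hm$valid_mask > 0
    vals <- c(vals, hm$values[keep])
    truth <- c(truth, sc$anomaly_mask[keep])
  }
  thr <- stats::quantile(vals, top_quantile)
  top <- vals > thr
  n_top <- sum(top)
  obs <- mean(truth[top])
  null_prec <- with_seed(seed, vapply(seq_len(n_draws), function(i)
    mean(truth[sample(length(truth), n_top)]), numeric(1)))
  list(precision = obs, null_mean = mean(null_prec),
       p_value = (1 + sum(null_prec >= obs)) / (1 + n_draws),
       n_scenes = length(scenes), n_top = n_top)
}
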