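# End-to-end pipeline: synth -> patch -> train -> score -> eval -> heatmap.
# A single nested config drives every stage; the fully expanded config is
# snapshotted verbatim into the run directory, each stage reads only the
# previous stage's declared outputs, and the final manifest lists every
# artifact with an md5 checksum so reruns can be compared bit-for-bit.

#' Default run configuration
#'
#' Returns the fully expanded nested configuration (every knob explicit, so
#' the serialized snapshot contains no hidden defaults). Sizes default to a
#' compact demonstration run; scale `data` and `training` up for real use.
#'
#' @param seed global seed; all stage seeds derive from it.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scene = list(height = 390L, width = 390L,
                 berry_count_range = c(6, 10),
                 illumination_sigma = 0.08,
                 anomaly_fraction = 0.35,
                 anomaly_kinds = c("discolor", "wither", "stem"),
                 background_tone = c(0.36, 0.30, 0.26)),
    data = list(n_train_healthy = 12L, n_eval_healthy = 4L,
                n_eval_anomalous = 4L, n_heatmap_scenes = 2L),
    patching = list(patch_size = 130L, coverage_threshold = 0.1,
                    target_size = 64L, min_anomalous_pixels = 30L),
    model = list(kind = "fpl_vae", latent_dim = 100L,
                 encoder_channels = c(32L, 64L, 128L, 256L),
                 decoder_channels = c(128L, 64L, 32L, 16L),
                 conv_channels = c(32L, 32L, 32L, 32L),
                 bottleneck_channels = 8L, leaky_slope = 0.2),
    loss = list(alpha = "auto", lambda_ = 1, metric = "mse",
                extractor = list(mode = "deterministic_random",
                                 channels = c(16L, 32L, 64L), seed = 7L,
                                 weights_path = NULL)),
    training = list(batch_size = 64L, val_batch_size = 16L,
                    learning_rate = 5e-4, max_epochs = 5L,
                    early_stop_patience = 10L, early_stop_min_delta = 1e-4,
                    val_fraction = 0.2),
    eval = list(bins = 30L),
    heatmap = list(metric = "mse", normalization = "minmax")),
    class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' Values in the file override the defaults of [default_run_config()];
#' everything else stays at its default, and the merged result is validated
#' before any work starts.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
load_run_config <- function(path) {
  check_that(file.exists(path), paste("no config file at", path),
             class = "berryvae_config_error")
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  # constructors are the validators; building them surfaces any bad field
  invisible(scene_spec(height = cfg$scene$height, width = cfg$scene$width,
                       berry_count_range = cfg$scene$berry_count_range,
                       illumination_sigma = cfg$scene$illumination_sigma,
                       anomaly_fraction = cfg$scene$anomaly_fraction,
                       anomaly_kinds = cfg$scene$anomaly_kinds,
                       background_tone = cfg$scene$background_tone))
  invisible(run_model_config(cfg))
  invisible(run_train_config(cfg))
  check_that(cfg$loss$metric %in% c("l1", "mse", "bce"),
             "loss.metric must be l1/mse/bce", class = "berryvae_config_error")
  cfg
}

run_scene_spec <- function(cfg, anomaly_fraction = 0)
  scene_spec(height = cfg$scene$height, width = cfg$scene$width,
             berry_count_range = cfg$scene$berry_count_range,
             illumination_sigma = cfg$scene$illumination_sigma,
             anomaly_fraction = anomaly_fraction,
             anomaly_kinds = cfg$scene$anomaly_kinds,
             background_tone = cfg$scene$background_tone)

run_model_config <- function(cfg) {
  if (cfg$model$kind == "fpl_vae")
    vae_config(input_size = cfg$patching$target_size,
               encoder_channels = cfg$model$encoder_channels,
               latent_dim = cfg$model$latent_dim,
               leaky_slope = cfg$model$leaky_slope,
               decoder_channels = cfg$model$decoder_channels)
  else
    ae_config(conv_channels = cfg$model$conv_channels,
              bottleneck_channels = cfg$model$bottleneck_channels,
              input_size = cfg$patching$target_size,
              leaky_slope = cfg$model$leaky_slope)
}

run_train_config <- function(cfg)
  train_config(alpha = if (identical(cfg$loss$alpha, "auto")) NULL
               else cfg$loss$alpha,
               batch_size = cfg$training$batch_size,
               val_batch_size = cfg$training$val_batch_size,
               learning_rate = cfg$training$learning_rate,
               max_epochs = cfg$training$max_epochs,
               early_stop_patience = cfg$training$early_stop_patience,
               early_stop_min_delta = cfg$training$early_stop_min_delta,
               val_fraction = cfg$training$val_fraction,
               seed = derive_seed(cfg$seed, 6),
               lambda_ = cfg$loss$lambda_)

run_extractor_spec <- function(cfg)
  feature_extractor_spec(mode = cfg$loss$extractor$mode,
                         channels = cfg$loss$extractor$channels,
                         seed = cfg$loss$extractor$seed,
                         weights_path = cfg$loss$extractor$weights_path,
                         input_size = cfg$patching$target_size)

# ---- stages -----------------------------------------------------------------

stage_synth <- function(cfg, out) {
  sp_train <- run_scene_spec(cfg, anomaly_fraction = 0)
  train_scenes <- generate_dataset(cfg$data$n_train_healthy, 0, sp_train,
                                   seed = derive_seed(cfg$seed, 1))
  sp_eval <- run_scene_spec(cfg, anomaly_fraction = cfg$scene$anomaly_fraction)
  eval_scenes <- generate_dataset(cfg$data$n_eval_healthy,
                                  cfg$data$n_eval_anomalous, sp_eval,
                                  seed = derive_seed(cfg$seed, 2))
  write_scene_set(train_scenes, file.path(out, "scenes", "train"))
  write_scene_set(eval_scenes, file.path(out, "scenes", "eval"))
  invisible(NULL)
}

pipeline_patches <- function(cfg, out, which = "train") {
  dir <- file.path(out, "scenes", which)
  check_that(file.exists(file.path(dir, "manifest.json")),
             sprintf("missing %s scenes; run the synth stage first", which),
             class = "berryvae_state_error")
  scenes <- load_scene_set(dir)
  unlist(lapply(scenes, function(sc) scene_patches(
    sc, cfg$patching$patch_size, cfg$patching$coverage_threshold,
    cfg$patching$target_size, cfg$patching$min_anomalous_pixels)$patches),
    recursive = FALSE)
}

stage_patch <- function(cfg, out) {
  dir.create(file.path(out, "patches"), recursive = TRUE, showWarnings = FALSE)
  for (which in c("train", "eval")) {
    pl <- pipeline_patches(cfg, out, which)
    write_patch_manifest(pl, file.path(out, "patches",
                                       paste0(which, "_manifest.jsonl")))
  }
  invisible(NULL)
}

stage_train <- function(cfg, out) {
  pl <- pipeline_patches(cfg, out, "train")
  pl <- Filter(function(p) p$label == "healthy", pl)
  sp <- split_healthy(pl, cfg$training$val_fraction,
                      seed = derive_seed(cfg$seed, 4))
  model <- build_model(cfg$model$kind, run_model_config(cfg),
                       seed = derive_seed(cfg$seed, 5))
  ext <- if (cfg$model$kind %in% c("fpl_vae", "fpl_ae"))
    run_extractor_spec(cfg) else NULL
  dir.create(file.path(out, "train"), recursive = TRUE, showWarnings = FALSE)
  rep <- train(model, sp$train, sp$val, run_train_config(cfg), extractor = ext,
               checkpoint_path = file.path(out, "train", "checkpoint.rds"))
  utils::write.csv(rep$history, file.path(out, "train", "history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    epochs_run = rep$epochs_run, best_epoch = rep$best_epoch,
    stopped_early = rep$stopped_early,
    extractor_fingerprint = rep$extractor_fingerprint,
    n_train = length(sp$train), n_val = length(sp$val),
    alpha = cfg$loss$alpha, lambda = cfg$loss$lambda_,
    seed = cfg$seed),
    file.path(out, "train", "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

pipeline_model <- function(out) {
  path <- file.path(out, "train", "checkpoint.rds")
  check_that(file.exists(path),
             "no trained checkpoint in run directory; run the train stage first",
             class = "berryvae_state_error")
  load_model(path)
}

stage_score <- function(cfg, out) {
  model <- pipeline_model(out)
  pl <- pipeline_patches(cfg, out, "eval")
  recs <- score_patches(model, pl, cfg$loss$metric)
  dir.create(file.path(out, "score"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(recs, file.path(out, "score", "scores.csv"),
                   row.names = FALSE)
  invisible(recs)
}

stage_eval <- function(cfg, out) {
  path <- file.path(out, "score", "scores.csv")
  check_that(file.exists(path),
             "no scores in run directory; run the score stage first",
             class = "berryvae_state_error")
  recs <- utils::read.csv(path, stringsAsFactors = FALSE)
  thr <- optimize_threshold(recs)
  strat <- evaluate_stratified(recs, thr$threshold)
  hist <- score_histogram(recs, cfg$eval$bins)
  dir.create(file.path(out, "eval"), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    threshold = thr$threshold, accuracy = thr$accuracy,
    tp = thr$tp, tn = thr$tn, fp = thr$fp, fn = thr$fn,
    metric = cfg$loss$metric,
    stratified = strat),
    file.path(out, "eval", "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(hist$counts, file.path(out, "eval", "histogram.csv"),
                   row.names = FALSE)
  invisible(thr)
}

stage_heatmap <- function(cfg, out) {
  model <- pipeline_model(out)
  dir <- file.path(out, "scenes", "eval")
  check_that(file.exists(file.path(dir, "manifest.json")),
             "missing eval scenes; run the synth stage first",
             class = "berryvae_state_error")
  scenes <- load_scene_set(dir)
  anom <- Filter(function(sc) sum(sc$anomaly_mask) > 0, scenes)
  anom <- head(anom, cfg$data$n_heatmap_scenes)
  dir.create(file.path(out, "heatmap"), recursive = TRUE, showWarnings = FALSE)
  prov <- list()
  for (sc in anom) {
    hm <- model_heatmap(model, sc$image, sc$berry_mask, cfg$heatmap$metric,
                        cfg$patching$patch_size,
                        cfg$patching$coverage_threshold, sc$scene_id)
    utils::write.csv(hm$values,
                     file.path(out, "heatmap", paste0(sc$scene_id, ".values.csv")),
                     row.names = FALSE)
    render_overlay(hm, sc$image, normalization = cfg$heatmap$normalization,
                   file = file.path(out, "heatmap",
                                    paste0(sc$scene_id, ".overlay.png")))
    prov[[sc$scene_id]] <- list(scene_id = sc$scene_id, metric = hm$metric,
                                max_value = max(hm$values),
                                covered_fraction = mean(hm$valid_mask))
  }
  jsonlite::write_json(prov, file.path(out, "heatmap", "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

PIPELINE_STAGES <- c("synth", "patch", "train", "score", "eval", "heatmap")

#' Run the anomaly-detection pipeline
#'
#' Executes the requested stages in order (synth, patch, train, score, eval,
#' heatmap), each stage reading only the outputs of earlier stages from the
#' run directory. The expanded config snapshot is written first; a manifest
#' with md5 checksums of every artifact is written last. Rerunning with the
#' same config and seed reproduces all artifacts bit-for-bit
#' (deterministic-random extractor, single-threaded).
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [load_run_config()]).
#' @param out_dir run directory (created if needed).
#' @param stages subset of the six stage names; default all.
#' @return list with `out_dir`, `manifest` (data.frame file/md5) and, when
#'   the eval stage ran, `metrics`.
#' @export
run_pipeline <- function(config, out_dir, stages = PIPELINE_STAGES) {
  config <- validate_run_config(config)
  check_that(all(stages %in% PIPELINE_STAGES),
             paste("unknown stage:", paste(setdiff(stages, PIPELINE_STAGES),
                                           collapse = ", ")),
             class = "berryvae_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  message(sprintf("run: seed=%d model=%s alpha=%s lambda=%g extractor=%s",
                  config$seed, config$model$kind,
                  as.character(config$loss$alpha),
                  config$loss$lambda_, config$loss$extractor$mode))
  status <- "complete"
  fail <- NULL
  for (st in PIPELINE_STAGES) {
    if (!st %in% stages) next
    ok <- tryCatch({
      switch(st,
             synth = stage_synth(config, out_dir),
             patch = stage_patch(config, out_dir),
             train = stage_train(config, out_dir),
             score = stage_score(config, out_dir),
             eval = stage_eval(config, out_dir),
             heatmap = stage_heatmap(config, out_dir))
      TRUE
    }, error = function(e) {
      status <<- "incomplete"
      fail <<- sprintf("stage '%s' failed: %s", st, conditionMessage(e))
      FALSE
    })
    if (!ok) break
  }
  manifest <- write_run_manifest(out_dir, status, fail)
  if (status != "complete")
    stop(fail, call. = FALSE)
  metrics_path <- file.path(out_dir, "eval", "metrics.json")
  metrics <- if (file.exists(metrics_path))
    jsonlite::read_json(metrics_path, simplifyVector = TRUE) else NULL
  list(out_dir = out_dir, manifest = manifest, metrics = metrics)
}

write_run_manifest <- function(out_dir, status = "complete", failure = NULL) {
  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(sums),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(list(status = status, failure = failure,
                            files = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
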