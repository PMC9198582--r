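# Shared fixtures: tiny models and scenes built in code at test time.

tiny_vae_config <- function(latent_dim = 6L)
  vae_config(input_size = 16, encoder_channels = c(2, 3, 4, 5),
             latent_dim = latent_dim, decoder_channels = c(4, 3, 2, 2))

tiny_ae_config <- function()
  ae_config(conv_channels = c(3, 3, 3, 3), bottleneck_channels = 2,
             input_size = 16)

tiny_extractor_spec <- function(seed = 5L)
  feature_extractor_spec(channels = c(3, 4), seed = seed, input_size = 16)

tiny_batch <- function(n = 3, size = 16, seed = 42) {
  set.seed(seed)
  matrix(runif(size * size * 3 * n), size * size * 3, n)
}

tiny_patches <- function(n = 20, size = 16, stage = c("early", "late"),
                         seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) berry_patch(
    array(runif(size * size * 3), c(size, size, 3)),
    origin = c(0, 0), source_size = size,
    scene_id = sprintf("t%03d", i), label = "healthy",
    stage_tag = stage[(i - 1) %% length(stage) + 1]))
}

small_scene <- function(seed = 1, stage = "early", anomaly_fraction = 0)
  generate_scene(scene_spec(height = 260, width = 260, stage_tag = stage,
                            anomaly_fraction = anomaly_fraction, seed = seed),
                 scene_id = paste0("sc", seed))

# brute-force oracle: best accuracy over every threshold placed between
# consecutive sorted scores (and outside the range)
brute_force_threshold <- function(scores, labels) {
  y <- labels == "anomalous"
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2,
            u[length(u)] + 1)
  accs <- vapply(cand, function(t) mean((scores > t) == y), numeric(1))
  list(accuracy = max(accs),
       threshold = cand[which(accs >= max(accs) - 1e-12)[1]])
}
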