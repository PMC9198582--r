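# Patch scoring and evaluation: reconstruction-loss scores, exact best-
# threshold search, growth-stage stratified accuracy, and score histograms.

#' Score patches by reconstruction loss
#'
#' Each patch is reconstructed with the deterministic scoring pass (eval-mode
#' batch norm; zero latent noise for the VAE) and scored with the spatial
#' mean of the chosen pixel-wise loss map.
#'
#' @param model a trained `berry_model` (scoring an untrained model is
#'   permitted only with `allow_untrained = TRUE`, e.g. for baselines).
#' @param patches a `patch_set` or list of `berry_patch`.
#' @param metric `"l1"`, `"mse"` or `"bce"`.
#' @param allow_untrained skip the trained-state check.
#' @return data.frame of score records: `patch_id`, `score`, `metric`,
#'   `label`, `stage_tag`.
#' @export
score_patches <- function(model, patches, metric = c("mse", "l1", "bce"),
                          allow_untrained = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "berry_model"))
  if (!allow_untrained)
    check_that(isTRUE(model$trained),
               "model is untrained; train or load a checkpoint first",
               class = "berryvae_state_error")
  pl <- as_patch_list(patches)
  check_that(length(pl) > 0, "no patches to score")
  # batch the forward passes for speed
  xb <- batch_from_arrays(lapply(pl, function(p) p$pixels))
  rec <- if (inherits(model, "fpl_vae"))
    forward_vae(model, xb, eps = 0, training = FALSE)$reconstruction
  else forward_ae(model, xb, training = FALSE)
  s <- model$config$input_size; ch <- model$config$input_channels
  scores <- vapply(seq_len(ncol(xb)), function(i) {
    pixel_loss_map(array(xb[, i], c(s, s, ch)),
                   array(rec[, i], c(s, s, ch)), metric)$score
  }, numeric(1))
  data.frame(patch_id = vapply(pl, function(p) p$patch_id, character(1)),
             score = scores, metric = metric,
             label = vapply(pl, function(p) p$label, character(1)),
             stage_tag = vapply(pl, function(p) p$stage_tag, character(1)),
             stringsAsFactors = FALSE)
}

#' Find the accuracy-maximising score threshold
#'
#' Exact search over every cut between consecutive sorted unique scores
#' (plus a below-minimum and an above-maximum cut). Classification rule:
#' `score > threshold` means anomalous. Accuracy ties are broken toward the
#' smaller threshold.
#'
#' @param records score records as returned by [score_patches()], with both
#'   labels present.
#' @return object of class `threshold_result`: `threshold`, `accuracy`,
#'   `tp`, `tn`, `fp`, `fn`, `metric`.
#' @export
optimize_threshold <- function(records) {
  check_that(all(c("score", "label") %in% names(records)),
             "records must have score and label columns")
  check_that(all(c("healthy", "anomalous") %in% records$label),
             "threshold optimisation needs both classes present")
  s <- records$score
  y <- records$label == "anomalous"
  u <- sort(unique(s))
  cand <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (thr in cand) {
    pred <- s > thr
    acc <- mean(pred == y)
    if (is.null(best) || acc > best$accuracy + 1e-12) {
      best <- list(threshold = thr, accuracy = acc,
                   tp = sum(pred & y), tn = sum(!pred & !y),
                   fp = sum(pred & !y), fn = sum(!pred & y))
    }
  }
  best$metric <- if ("metric" %in% names(records)) records$metric[1] else NA
  class(best) <- "threshold_result"
  best
}

#' Evaluate accuracy per stratum at a fixed threshold
#'
#' The joint row uses all records; stratum rows reuse the same global
#' threshold, so counts sum across strata to the joint counts.
#'
#' @param records score records.
#' @param threshold decision threshold (`score > threshold` = anomalous).
#' @param strata name of the stratification column (default `"stage_tag"`).
#' @return data.frame with one row per stratum plus a `"joint"` row:
#'   `stratum`, `n`, `accuracy`, `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_stratified <- function(records, threshold, strata = "stage_tag") {
  check_that(strata %in% names(records),
             sprintf("unknown stratum field '%s'", strata))
  eval_rows <- function(df, name) {
    pred <- df$score > threshold
    y <- df$label == "anomalous"
    data.frame(stratum = name, n = nrow(df), accuracy = mean(pred == y),
               tp = sum(pred & y), tn = sum(!pred & !y),
               fp = sum(pred & !y), fn = sum(!pred & y),
               stringsAsFactors = FALSE)
  }
  out <- eval_rows(records, "joint")
  for (st in sort(unique(records[[strata]])))
    out <- rbind(out, eval_rows(records[records[[strata]] == st, ], st))
  rownames(out) <- NULL
  out
}

#' Histogram of scores per label
#'
#' Shared bin edges across labels; counts per bin per label sum to the
#' per-label record counts.
#'
#' @param records score records.
#' @param bins number of bins (>= 2).
#' @return list with `breaks` (length bins+1) and `counts` (data.frame:
#'   label, bin, left, right, count).
#' @export
score_histogram <- function(records, bins = 30L) {
  check_that(bins >= 2, "bins must be >= 2")
  rng <- range(records$score)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- do.call(rbind, lapply(unique(records$label), function(lb) {
    sc <- records$score[records$label == lb]
    idx <- pmin(pmax(findInterval(sc, breaks, rightmost.closed = TRUE), 1), bins)
    data.frame(label = lb, bin = seq_len(bins),
               left = head(breaks, -1), right = tail(breaks, -1),
               count = tabulate(idx, bins), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(breaks = breaks, counts = counts)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result thr=%.5g acc=%.3f (tp %d tn %d fp %d fn %d)>\n",
              x$threshold, x$accuracy, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
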