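# Threshold optimisation, stratified evaluation, histograms.

make_records <- function(scores, labels, stage = "early")
  data.frame(patch_id = sprintf("p%03d", seq_along(scores)), score = scores,
             metric = "mse", label = labels,
             stage_tag = rep(stage, length.out = length(scores)),
             stringsAsFactors = FALSE)

test_that("optimize_threshold finds the separating cut on separable scores", {
  r <- make_records(c(0.1, 0.2, 0.3, 0.5, 0.6),
                    c("healthy", "healthy", "healthy", "anomalous", "anomalous"))
  res <- optimize_threshold(r)
  expect_equal(res$accuracy, 1)
  expect_equal(res$threshold, 0.4)
  expect_equal(res$tp + res$tn + res$fp + res$fn, 5)
  expect_equal(res$accuracy, (res$tp + res$tn) / 5)
})

test_that("optimize_threshold handles no-separation and degenerate inputs", {
  # perfectly interleaved equal scores: majority cut, accuracy 0.5
  r <- make_records(rep(c(1, 1), 4), rep(c("healthy", "anomalous"), 4))
  expect_equal(optimize_threshold(r)$accuracy, 0.5)
  expect_error(optimize_threshold(make_records(1:3, rep("healthy", 3))),
               "both classes")
})

test_that("optimize_threshold equals exhaustive search on random instances", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), sample(c(1, 2, 3), 1))  # force ties sometimes
    labels <- sample(c("healthy", "anomalous"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("healthy", "anomalous")
    res <- optimize_threshold(make_records(scores, labels))
    bf <- brute_force_threshold(scores, labels)
    expect_equal(res$accuracy, bf$accuracy)
    # accuracy never below the majority-class proportion
    expect_gte(res$accuracy, max(mean(labels == "healthy"),
                                 mean(labels == "anomalous")) - 1e-12)
  }
})

test_that("best accuracy is invariant to strictly increasing score transforms", {
  set.seed(21)
  scores <- runif(60)
  labels <- sample(c("healthy", "anomalous"), 60, replace = TRUE)
  labels[1:2] <- c("healthy", "anomalous")
  a1 <- optimize_threshold(make_records(scores, labels))$accuracy
  a2 <- optimize_threshold(make_records(exp(3 * scores), labels))$accuracy
  expect_equal(a1, a2)
})

test_that("adding a correctly-classified record never lowers best accuracy", {
  set.seed(22)
  for (i in 1:20) {
    scores <- runif(30)
    labels <- sample(c("healthy", "anomalous"), 30, replace = TRUE)
    labels[1:2] <- c("healthy", "anomalous")
    r <- make_records(scores, labels)
    res <- optimize_threshold(r)
    extra <- if (runif(1) < 0.5)
      make_records(max(scores) + 1, "anomalous")
    else make_records(min(scores) - 1, "healthy")
    extra$patch_id <- "extra"
    res2 <- optimize_threshold(rbind(r, extra))
    n1 <- nrow(r); n2 <- n1 + 1
    expect_gte(res2$accuracy * n2, res$accuracy * n1)
  }
})

test_that("stratified evaluation reuses the global threshold and is additive", {
  r <- make_records(c(0.1, 0.6, 0.2, 0.7, 0.15, 0.65),
                    rep(c("healthy", "anomalous"), 3),
                    stage = c("early", "early", "early", "late", "late", "late"))
  res <- optimize_threshold(r)
  tab <- evaluate_stratified(r, res$threshold)
  joint <- tab[tab$stratum == "joint", ]
  expect_equal(joint$tp, sum(tab$tp[tab$stratum != "joint"]))
  expect_equal(joint$tn, sum(tab$tn[tab$stratum != "joint"]))
  expect_equal(joint$n, 6)
  # single stratum: joint equals the stratum row
  r1 <- make_records(c(0.1, 0.9), c("healthy", "anomalous"), stage = "early")
  t1 <- evaluate_stratified(r1, 0.5)
  expect_equal(t1$accuracy[1], t1$accuracy[2])
  # joint accuracy is the count-weighted mean of stratum accuracies
  w <- tab$n[tab$stratum != "joint"]
  expect_equal(joint$accuracy,
               sum(tab$accuracy[tab$stratum != "joint"] * w) / sum(w))
  expect_error(evaluate_stratified(r, 0.5, strata = "nope"), "unknown stratum")
})

test_that("score histograms conserve counts and share bin edges", {
  set.seed(23)
  r <- make_records(c(rnorm(40, 1), rnorm(25, 3)),
                    c(rep("healthy", 40), rep("anomalous", 25)))
  h <- score_histogram(r, bins = 12)
  expect_equal(length(h$breaks), 13)
  agg <- tapply(h$counts$count, h$counts$label, sum)
  expect_equal(unname(agg[["healthy"]]), 40)
  expect_equal(unname(agg[["anomalous"]]), 25)
  # all-equal scores occupy a single bin
  h1 <- score_histogram(make_records(rep(2, 9), rep(c("healthy", "anomalous"),
                                                    length.out = 9)), bins = 5)
  occ <- tapply(h1$counts$count, h1$counts$bin, sum)
  expect_equal(sum(occ > 0), 1)
  expect_error(score_histogram(r, bins = 1), "bins")
})
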