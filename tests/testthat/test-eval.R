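test_that("AUC handles perfect ranking, total ties and the worked example", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(.1, .4, .35, .8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(.1, .2), c(1, 1)), "single class")
})

test_that("rank AUC equals exhaustive pair counting on random instances", {
  set.seed(101)
  for (r in 1:100) {
    n <- sample(5:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- if (r %% 2 == 0) round(runif(n), 1) else runif(n)  # with ties
    expect_equal(roc_auc(probs, labels), auc_pair_oracle(probs, labels),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with the pROC reference implementation", {
  set.seed(103)
  for (r in 1:10) {
    n <- 150
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(probs, labels), ref, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(107)
  probs <- runif(80)
  labels <- rbinom(80, 1, probs)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  expect_equal(roc_auc(plogis(5 * probs - 2), labels),
               roc_auc(probs, labels))
})

test_that("the optimal threshold maximizes sensitivity plus specificity", {
  # perfectly separated: gap midpoint, se = spe = 1
  thr <- optimal_threshold(c(.1, .2, .8, .9), c(0, 0, 1, 1))
  expect_equal(thr, 0.5)
  cs <- confusion_stats(c(.1, .2, .8, .9), c(0, 0, 1, 1), thr)
  expect_equal(cs$sensitivity + cs$specificity, 2)

  # worked example: best achievable se+spe is 1.5
  probs <- c(.1, .4, .35, .8); labels <- c(0, 0, 1, 1)
  thr <- optimal_threshold(probs, labels)
  cs <- confusion_stats(probs, labels, thr)
  expect_equal(cs$sensitivity + cs$specificity, 1.5)
  expect_equal(best_sesp_oracle(probs, labels), 1.5)

  expect_error(optimal_threshold(c(.1, .2), c(1, 1)), "single class")
})

test_that("threshold scan equals the exhaustive cut-off oracle", {
  set.seed(109)
  for (r in 1:50) {
    n <- sample(5:120, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- if (r %% 2 == 0) round(runif(n), 1) else runif(n)
    thr <- optimal_threshold(probs, labels)
    cs <- confusion_stats(probs, labels, thr)
    expect_equal(cs$sensitivity + cs$specificity,
                 best_sesp_oracle(probs, labels), tolerance = 1e-12)
    # raw scores may sit exactly at 0 or 1; model probabilities are clipped
    # into the open interval upstream, keeping pipeline thresholds in (0,1)
    expect_true(thr >= 0 && thr <= 1)
  }
})

test_that("with labels independent of scores max(se+spe) stays near 1", {
  set.seed(113)
  probs <- runif(5000)
  labels <- rbinom(5000, 1, 0.5)
  thr <- optimal_threshold(probs, labels)
  cs <- confusion_stats(probs, labels, thr)
  expect_lt(cs$sensitivity + cs$specificity, 1.1)
})

test_that("confusion statistics follow the >= classification rule", {
  probs <- c(rep(.8, 9), rep(.2, 1), rep(.1, 7), rep(.9, 3))
  labels <- c(rep(1, 10), rep(0, 10))
  cs <- confusion_stats(probs, labels, 0.5)
  expect_equal(cs[c("tp", "fn", "tn", "fp")], list(tp = 9, fn = 1, tn = 7, fp = 3))
  expect_equal(cs$sensitivity, 0.9)
  expect_equal(cs$specificity, 0.7)
  expect_equal(cs$tp + cs$fp + cs$tn + cs$fn, 20)

  all_in <- confusion_stats(probs, labels, 0)
  expect_equal(c(all_in$sensitivity, all_in$specificity), c(1, 0))
  all_out <- confusion_stats(probs, labels, 1 + 1e-9)
  expect_equal(c(all_out$sensitivity, all_out$specificity), c(0, 1))
})

test_that("accuracy bands follow the conventional AUC cut points", {
  expect_identical(accuracy_band(c(0.87, 0.91, 0.5, 0.3, 0.6, 0.7, 0.9)),
                   c("useful", "highly_accurate", "no_power", "no_power",
                     "poor", "useful", "useful"))
  expect_error(accuracy_band(1.2))
})

test_that("evaluate_predictions bundles the three statistics coherently", {
  set.seed(127)
  probs <- runif(200)
  labels <- rbinom(200, 1, probs)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  ev <- evaluate_predictions(probs, labels)
  expect_equal(ev$threshold, optimal_threshold(probs, labels))
  expect_equal(ev$auc, roc_auc(probs, labels))
  expect_equal(ev$sensitivity, ev$tp / (ev$tp + ev$fn))
  expect_equal(ev$specificity, ev$tn / (ev$tn + ev$fp))
  expect_identical(ev$accuracy_band, accuracy_band(ev$auc))
  # fixed-threshold variant
  ev2 <- evaluate_predictions(probs, labels, threshold = 0.5)
  expect_equal(ev2$threshold, 0.5)
})

test_that("null replicates are reproducible and concentrated at large n", {
  cs <- small_world(n = 4000, seed = 131, prevalence = 0.4,
                    beta = c(sst_avg = -1.5, wh_avg = 2.5))
  ns <- null_replicates(cs, "H", 0.2, n_reps = 10, base_seed = 50,
                        selected = c("sst_avg", "wh_avg"))
  ns2 <- null_replicates(cs, "H", 0.2, n_reps = 10, base_seed = 50,
                         selected = c("sst_avg", "wh_avg"))
  expect_identical(ns$summary, ns2$summary)
  expect_identical(ns$n_reps, 10L)
  expect_identical(nrow(ns$replicates), 10L)
  auc_sd <- ns$summary$sd[ns$summary$metric == "AUC"]
  expect_lt(auc_sd, 0.05)
  expect_error(null_replicates(cs, "H", 0.2, n_reps = 1))
})

test_that("null-model AUC increases with signal strength", {
  mean_auc <- function(scale) {
    cs <- small_world(n = 3000, seed = 137, prevalence = 0.35,
                      beta = c(sst_avg = -1, wh_avg = 2) * scale)
    ns <- null_replicates(cs, "H", 0.2, n_reps = 4, base_seed = 60,
                          selected = c("sst_avg", "wh_avg"))
    ns$summary$mean[ns$summary$metric == "AUC"]
  }
  aucs <- c(mean_auc(0.3), mean_auc(1), mean_auc(3))
  expect_true(all(diff(aucs) > 0))
})
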