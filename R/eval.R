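#' Area under the ROC curve (rank formulation)
#'
#' Threshold-free ranking accuracy of predicted probabilities against
#' observed 0/1 labels, computed via the Mann-Whitney rank statistic: tied
#' probabilities contribute 1/2 per tied positive-negative pair. 0.5 is no
#' discrimination, 1 is perfect.
#'
#' @param probs numeric vector of predicted probabilities (any monotone score
#'   works; AUC is invariant to strictly increasing transforms).
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: labels contain a single class")
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Candidate cut-offs: midpoints between consecutive distinct sorted
# probabilities, plus boundary candidates below the minimum and above the
# maximum (all within (0,1) for probability inputs).
threshold_candidates <- function(probs) {
  pu <- sort(unique(probs))
  (c(0, pu) + c(pu, 1)) / 2
}

# Sensitivity and specificity at each candidate, computed by suffix counts
# over the sorted distinct probabilities (O(n log n)).
se_spe_curve <- function(probs, labels) {
  pu <- sort(unique(probs))
  idx <- match(probs, pu)
  pos_at <- as.numeric(tabulate(idx[labels == 1], nbins = length(pu)))
  tot_at <- as.numeric(tabulate(idx, nbins = length(pu)))
  n_pos <- sum(labels == 1)
  n_neg <- length(labels) - n_pos
  # candidate j (j = 0..K) predicts presence for probs >= candidate, i.e.
  # for the distinct values pu[j+1], ..., pu[K]
  tp_suffix <- rev(cumsum(rev(pos_at)))            # tp when cutting below pu[j]
  pp_suffix <- rev(cumsum(rev(tot_at)))            # predicted positives
  tp <- c(tp_suffix, 0)
  pp <- c(pp_suffix, 0)
  fp <- pp - tp
  data.frame(threshold = threshold_candidates(probs),
             sensitivity = tp / n_pos,
             specificity = (n_neg - fp) / n_neg)
}

#' Threshold maximizing sensitivity plus specificity
#'
#' Scans candidate cut-offs (midpoints between consecutive distinct sorted
#' probabilities, plus the boundaries) and returns the one maximizing
#' `sensitivity + specificity` under the presence-when-`prob >= threshold`
#' rule. Ties go to the smallest threshold, which favours sensitivity.
#'
#' @inheritParams roc_auc
#' @return the optimal threshold (single numeric in (0, 1)).
#' @export
optimal_threshold <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("threshold undefined: labels contain a single class")
  }
  curve <- se_spe_curve(probs, labels)
  obj <- curve$sensitivity + curve$specificity
  curve$threshold[which.max(obj)]  # which.max -> first (smallest) on ties
}

#' Confusion-matrix statistics at a threshold
#'
#' Counts true/false positives/negatives with the presence-when-
#' `prob >= threshold` rule and derives sensitivity (true positive rate) and
#' specificity (true negative rate).
#'
#' @inheritParams roc_auc
#' @param threshold classification cut-off in `[0, 1]` (values above 1 make
#'   every prediction absent).
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
confusion_stats <- function(probs, labels, threshold) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)),
            threshold >= 0)
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Accuracy band of an AUC value
#'
#' The conventional interpretation bands: AUC above 0.9 is highly accurate,
#' 0.7-0.9 useful, below 0.7 poorly accurate, and at or below 0.5 the model
#' has no predictive power.
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return character vector: `"highly_accurate"`, `"useful"`, `"poor"` or
#'   `"no_power"`.
#' @export
accuracy_band <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  ifelse(auc <= 0.5, "no_power",
         ifelse(auc < 0.7, "poor",
                ifelse(auc <= 0.9, "useful", "highly_accurate")))
}

#' Evaluate predictions on held-out data
#'
#' Bundles the three validation statistics: AUC, the optimal threshold
#' (chosen on these predictions unless supplied), and sensitivity /
#' specificity with confusion counts at that threshold.
#'
#' @inheritParams roc_auc
#' @param threshold optional fixed cut-off; default picks
#'   [optimal_threshold()] on `probs`/`labels`.
#' @return list of class `hdm_eval`: `auc`, `threshold`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `tn`, `fn`, `accuracy_band`.
#' @export
evaluate_predictions <- function(probs, labels, threshold = NULL) {
  auc <- roc_auc(probs, labels)
  if (is.null(threshold)) threshold <- optimal_threshold(probs, labels)
  cs <- confusion_stats(probs, labels, threshold)
  structure(c(list(auc = auc, threshold = threshold), cs,
              list(accuracy_band = accuracy_band(auc))),
            class = "hdm_eval")
}

#' @export
print.hdm_eval <- function(x, ...) {
  cat(sprintf("<hdm_eval> AUC %.3f (%s), threshold %.3f, se %.3f, spe %.3f\n",
              x$auc, x$accuracy_band, x$threshold,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Null-model replicates for one habitat and sampling fraction
#'
#' Runs the full fit-and-validate pipeline on `n_reps` random training
#' splits (seeds `base_seed .. base_seed + n_reps - 1`) and summarizes
#' explained deviance, AUC, sensitivity and specificity as mean and standard
#' deviation over replicates. Degenerate replicates (training response all 0
#' or all 1) are excluded and counted.
#'
#' @param data a [coastline] with the habitat column.
#' @param habitat habitat code.
#' @param fraction sampling fraction.
#' @param n_reps number of replicates (default 10).
#' @param base_seed seed of the first replicate.
#' @param selected predictor terms to fit; default selects by AIC on the full
#'   dataset first (see [select_model_aic()]).
#' @return list of class `null_summary`: `summary` data.frame (metric, mean,
#'   sd), `n_reps`, `n_degenerate`, `replicates` (per-replicate metrics).
#' @export
null_replicates <- function(data, habitat, fraction, n_reps = 10L,
                            base_seed = 1L, selected = NULL) {
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 2L, habitat %in% habitat_codes(data))
  y_all <- as.data.frame(data)[[habitat]]
  if (is.null(selected)) {
    selected <- select_model_aic(data, y_all)$selected
  }
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    res <- run_scenario(data, habitat,
                        list(strategy = "random", fraction = fraction,
                             seed = base_seed + r - 1L),
                        selected = selected)
    rows[[r]] <- res
  }
  reps <- do.call(rbind, rows)
  ok <- reps$status == "ok"
  if (!any(ok)) stop("all null replicates degenerate")
  metrics <- c("D2", "AUC", "sensitivity", "specificity")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reps[[m]][ok]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(reps[[m]][ok]), numeric(1)),
    row.names = NULL
  )
  structure(list(summary = summ, n_reps = n_reps,
                 n_degenerate = sum(!ok), replicates = reps),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("<null_summary> %d replicates (%d degenerate)\n",
              x$n_reps, x$n_degenerate))
  print(x$summary)
  invisible(x)
}
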