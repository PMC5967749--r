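# Shared fixture builders. All data is generated in code at test time.

# A small synthetic world with one widespread habitat layer.
small_world <- function(n = 2000, seed = 11, prevalence = 0.4,
                        pattern = "widespread",
                        beta = c(sst_avg = -1, wh_avg = 2),
                        strength = 2, code = "H") {
  cfg <- coast_config(n = n, seed = seed)
  env <- generate_environment(cfg)
  generate_habitat(env,
                   habitat_spec(code, prevalence, pattern, beta = beta,
                                pattern_strength = strength),
                   seed = seed + 1)
}

# Minimal handcrafted coastline data.frame (regularly spaced, due south).
tiny_coast_df <- function(n, habitats = list()) {
  df <- data.frame(
    x = rep(0, n),
    y = -10 * (seq_len(n) - 1),
    sst_avg = seq(16.8, 18.7, length.out = n),
    wh_avg = rep(0.5, n),
    wh_min = rep(0.05, n),
    slope_class = rep_len(1:5, n),
    geology = rep_len(c("metamorphic", "plutonic"), n),
    substrate = rep_len(c("natural", "artificial"), n),
    stringsAsFactors = FALSE
  )
  for (h in names(habitats)) df[[h]] <- habitats[[h]]
  df
}

# Exhaustive pair-counting AUC oracle: every positive-negative pair scores
# 1 if ranked correctly, 1/2 on ties.
auc_pair_oracle <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive threshold oracle: best achievable se+spe over every distinct
# probability used directly as a cut-off (plus 0 and above-max).
best_sesp_oracle <- function(probs, labels) {
  cands <- c(0, sort(unique(probs)), max(probs) + 1)
  best <- -Inf
  for (t in cands) {
    cs <- confusion_stats(probs, labels, t)
    best <- max(best, cs$sensitivity + cs$specificity)
  }
  best
}

# Count maximal runs of consecutive integers in a sorted index set.
count_runs <- function(idx) {
  if (length(idx) == 0) return(0L)
  sum(diff(idx) > 1L) + 1L
}
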