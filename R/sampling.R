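#' Training sample size for a sampling fraction
#'
#' Number of points in a training sample covering `fraction` of an `n`-point
#' coastline: `fraction * n` rounded to the nearest integer, halves away from
#' zero.
#'
#' @param n total point count.
#' @param fraction sampling fraction in (0, 1).
#' @return integer sample size.
#' @export
sample_size <- function(n, fraction) {
  stopifnot(n >= 1, fraction > 0, fraction < 1)
  m <- as.integer(round_half_up(fraction * n))
  if (m == 0L) stop("empty training sample: fraction too small for n")
  m
}

new_split <- function(train, n, strategy, fraction, case = NA_character_,
                      k = NA_integer_, seed = NA_integer_) {
  train <- sort(as.integer(train))
  structure(list(
    train = train,
    test = setdiff(0:(n - 1L), train),
    n = as.integer(n), strategy = strategy, fraction = fraction,
    case = case, k = k, seed = seed
  ), class = "sample_split")
}

#' @export
print.sample_split <- function(x, ...) {
  cat(sprintf("<sample_split> %s %d%%%s: %d train / %d test of %d\n",
              x$strategy, round(100 * x$fraction),
              if (!is.na(x$case)) paste0(" ", x$case) else "",
              length(x$train), length(x$test), x$n))
  invisible(x)
}

#' Aggregated (single-stretch) training split
#'
#' Training data is one contiguous block of neighboring coastline points.
#' Four reproducible placements span the coast: cases 1-4 start the block at
#' positions 0, 25%, 50% and 75% of the chain, clipped toward the start when
#' the block would overrun the end.
#'
#' @param n coastline size.
#' @param fraction sampling fraction in (0, 1).
#' @param case `"case1"`..`"case4"` (or 1..4).
#' @return a `sample_split` with 0-based `train`/`test` index sets.
#' @export
aggregated_split <- function(n, fraction, case = "case1") {
  if (is.numeric(case)) case <- paste0("case", case)
  stopifnot(case %in% paste0("case", 1:4))
  m <- sample_size(n, fraction)
  if (m >= n) stop("degenerate split: training sample covers whole coastline")
  frac_start <- c(case1 = 0, case2 = 0.25, case3 = 0.5, case4 = 0.75)[[case]]
  start <- as.integer(round_half_up(frac_start * n))
  start <- min(start, n - m)  # clip so the block fits
  new_split(start:(start + m - 1L), n, "aggregated", fraction, case = case)
}

#' Interspaced (regularly spaced stretches) training split
#'
#' Training data is `k` contiguous stretches of near-equal length (within one
#' point), their starts evenly spaced along the chain at offsets
#' `round(j * n / k)`, alternating with unselected coast. At fraction 0.5 the
#' selected and unselected runs have equal length. The design keeps a minimum
#' of 5 stretches.
#'
#' @param n coastline size.
#' @param fraction sampling fraction in (0, 1).
#' @param k number of stretches (>= 5).
#' @return a `sample_split`.
#' @export
interspaced_split <- function(n, fraction, k = 5L) {
  k <- as.integer(k)
  stopifnot(k >= 5L)
  m <- sample_size(n, fraction)
  if (k > m) stop("more stretches than training points: reduce k")
  base_len <- m %/% k
  lens <- base_len + as.integer(seq_len(k) <= m %% k)
  starts <- as.integer(round_half_up((seq_len(k) - 1L) * n / k))
  ends <- starts + lens  # exclusive
  next_start <- c(starts[-1L], n)
  if (any(ends > next_start)) {
    stop("stretches would overlap: fraction too high for k; use a smaller k")
  }
  train <- unlist(lapply(seq_len(k), function(j) {
    if (lens[j] == 0L) integer(0) else starts[j]:(ends[j] - 1L)
  }))
  new_split(train, n, "interspaced", fraction, k = k)
}

#' Random (null-model) training split
#'
#' Uniform sample of points without replacement, the reference design against
#' which the spatial strategies are compared.
#'
#' @param n coastline size.
#' @param fraction sampling fraction in (0, 1).
#' @param seed integer seed; same seed, same split.
#' @return a `sample_split`.
#' @export
random_split <- function(n, fraction, seed = 1L) {
  m <- sample_size(n, fraction)
  train <- with_seed(seed, sample.int(n, m)) - 1L
  new_split(train, n, "random", fraction, seed = as.integer(seed))
}

#' Build the split for one scenario row
#'
#' @param n coastline size.
#' @param scenario one row of [scenario_grid()] or [null_grid()] (or a list
#'   with `strategy`, `fraction`, and `case`/`k`/`seed`).
#' @return a `sample_split`.
#' @export
make_split <- function(n, scenario) {
  switch(as.character(scenario$strategy),
    aggregated = aggregated_split(n, scenario$fraction, scenario$case),
    interspaced = interspaced_split(n, scenario$fraction,
                                    if (is.null(scenario$k) || is.na(scenario$k)) 5L
                                    else scenario$k),
    random = random_split(n, scenario$fraction, scenario$seed),
    stop("unknown strategy: ", scenario$strategy))
}

#' The 19-scenario experimental grid
#'
#' The deterministic set of non-null sampling scenarios run per habitat:
#' interspaced at 10-50% (5 scenarios), aggregated case 1 at 10-50% (5), and
#' aggregated cases 2-4 at 20-40% (9), totaling 19.
#'
#' @param k interspaced stretch count (default 5).
#' @return data.frame with columns `strategy`, `fraction`, `case`, `k`.
#' @export
scenario_grid <- function(k = 5L) {
  fr_all <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  fr_mid <- c(0.2, 0.3, 0.4)
  rbind(
    data.frame(strategy = "interspaced", fraction = fr_all,
               case = NA_character_, k = as.integer(k)),
    data.frame(strategy = "aggregated", fraction = fr_all,
               case = "case1", k = NA_integer_),
    expand.grid(strategy = "aggregated", fraction = fr_mid,
                case = paste0("case", 2:4), k = NA_integer_,
                stringsAsFactors = FALSE)[c("strategy", "fraction", "case", "k")]
  )
}

#' Null-model scenario grid
#'
#' Random splits at each sampling fraction, replicated with consecutive
#' seeds: 5 fractions x 10 replicates = 50 scenarios by default.
#'
#' @param fractions sampling fractions.
#' @param n_reps replicates per fraction (default 10).
#' @param base_seed first seed; replicate `r` at a fraction uses
#'   `base_seed + (r - 1)` offset by the fraction position.
#' @return data.frame with columns `strategy`, `fraction`, `seed`, `rep`.
#' @export
null_grid <- function(fractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      n_reps = 10L, base_seed = 1000L) {
  g <- expand.grid(rep = seq_len(n_reps), fraction = fractions)
  g$strategy <- "random"
  g$seed <- as.integer(base_seed + (match(g$fraction, fractions) - 1L) * n_reps +
                         g$rep - 1L)
  g[c("strategy", "fraction", "seed", "rep")]
}

#' Extract training/test rows of a dataset for a split
#'
#' @param data a [coastline] (or data.frame with rows in index order).
#' @param split a `sample_split`.
#' @param which `"train"` or `"test"`.
#' @return the corresponding rows as a data.frame.
#' @export
split_rows <- function(data, split, which = c("train", "test")) {
  which <- match.arg(which)
  stopifnot(nrow(data) == split$n)
  as.data.frame(data)[split[[which]] + 1L, , drop = FALSE]
}
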