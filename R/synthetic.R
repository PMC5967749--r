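#' Configuration for synthetic coastline generation
#'
#' Describes a simulated 1-D coastal chain: point count and spacing, the
#' north-to-south sea-surface temperature gradient, wave-height ranges, the
#' lag-1 autocorrelation of the continuous environmental noise, and the
#' expected run length of categorical (slope / geology / substrate) segments.
#' Defaults mirror the scale and printed predictor ranges of the Catalan
#' coastline database the pipeline is designed around: 16,098 points at 10 m
#' spacing, SST 16.8-18.7 deg C, mean wave height 0.02-0.9 m, minimum wave
#' height 0.01-0.07 m.
#'
#' @param n number of coastline points (>= 10).
#' @param sst_range,wh_avg_range,wh_min_range `(low, high)` ranges.
#' @param ar_rho lag-1 autocorrelation of the AR(1) environmental noise, in
#'   `[0, 1)`. The default 0.995 makes fields vary on a multi-hundred-point
#'   (kilometer) scale, as slowly varying coastal fields do.
#' @param segment_length expected run length (points) of categorical
#'   segments; default 200 points = 2 km at 10 m spacing.
#' @param sst_noise_sd marginal SD (deg C) of the AR(1) noise added to the
#'   SST gradient.
#' @param spacing inter-point distance in meters.
#' @param seed integer RNG seed.
#' @return a `coast_config` list.
#' @export
coast_config <- function(n = 16098, sst_range = c(16.8, 18.7),
                         wh_avg_range = c(0.02, 0.9),
                         wh_min_range = c(0.01, 0.07),
                         ar_rho = 0.995, segment_length = 200,
                         sst_noise_sd = 0.2, spacing = 10, seed = 1L) {
  stopifnot(n >= 10,
            length(sst_range) == 2, sst_range[1] < sst_range[2],
            length(wh_avg_range) == 2, wh_avg_range[1] < wh_avg_range[2],
            length(wh_min_range) == 2, wh_min_range[1] < wh_min_range[2],
            ar_rho >= 0, ar_rho < 1,
            segment_length >= 1, spacing > 0)
  structure(list(n = as.integer(n), sst_range = sst_range,
                 wh_avg_range = wh_avg_range, wh_min_range = wh_min_range,
                 ar_rho = ar_rho, segment_length = segment_length,
                 sst_noise_sd = sst_noise_sd, spacing = spacing,
                 seed = as.integer(seed)),
            class = "coast_config")
}

#' Specification of one synthetic habitat layer
#'
#' A habitat layer is generated from the same model family the pipeline fits:
#' occurrence is Bernoulli with probability `plogis(intercept + X beta +
#' pattern offset)`, where `X` is the dummy-coded environmental design and
#' the pattern offset encodes along-coast distribution patterns that the
#' environmental predictors alone do not carry:
#' \describe{
#'   \item{widespread}{no offset; occurrence tracks the environment only.}
#'   \item{localized_north}{`+pattern_strength` on the logit for points in
#'     the northern half of the chain, `-pattern_strength` in the south.}
#'   \item{localized_south}{the mirror image.}
#'   \item{rare_scattered}{no offset and `beta` shrunk toward zero (factor
#'     0.25) so the few occurrences spread along the whole coast.}
#' }
#' The intercept is calibrated afterwards (see [calibrate_intercept()]) so
#' the mean occurrence probability hits `target_prevalence`.
#'
#' @param code habitat column name.
#' @param target_prevalence fraction of points occupied, in (0, 1).
#' @param pattern one of `"widespread"`, `"localized_north"`,
#'   `"localized_south"`, `"rare_scattered"`.
#' @param beta named numeric vector of logit-scale coefficients on design
#'   columns (continuous predictor names, or dummy column names such as
#'   `"geologyplutonic"` against the generator's fixed references: slope
#'   class 1, metamorphic geology, natural substrate).
#' @param pattern_strength logit offset magnitude for localized patterns.
#' @return a `habitat_spec` list.
#' @export
habitat_spec <- function(code, target_prevalence,
                         pattern = c("widespread", "localized_north",
                                     "localized_south", "rare_scattered"),
                         beta = NULL, pattern_strength = 2) {
  pattern <- match.arg(pattern)
  stopifnot(target_prevalence > 0, target_prevalence < 1,
            pattern_strength >= 0)
  if (is.null(beta)) beta <- c(sst_avg = -1, wh_avg = 2)
  stopifnot(!is.null(names(beta)), all(nzchar(names(beta))))
  structure(list(code = code, target_prevalence = target_prevalence,
                 pattern = pattern, beta = beta,
                 pattern_strength = pattern_strength),
            class = "habitat_spec")
}

# Fixed reference levels used by the generator so true coefficients are
# well-defined regardless of realized category frequencies.
generator_refs <- function() {
  list(slope_class = "1", geology = "metamorphic", substrate = "natural")
}

#' Default synthetic habitat layers
#'
#' Six layers mirroring the prevalence and distribution patterns of the
#' modeled Catalan littoral habitats: two abundant northern habitats (47.9%
#' and 34.9%), an uncommon localized northern one (7.2%), an uncommon
#' localized southern one (3.3%), a rare scattered one (0.7%), and an
#' abundant widespread infralittoral one (28.4%).
#'
#' @return named list of [habitat_spec] objects.
#' @export
default_habitat_specs <- function() {
  list(
    Riv = habitat_spec("Riv", 0.479, "localized_north",
                       beta = c(sst_avg = -1.0, wh_avg = 2.0,
                                geologyplutonic = 1.0),
                       pattern_strength = 2),
    Lby = habitat_spec("Lby", 0.349, "localized_north",
                       beta = c(sst_avg = -0.8, wh_avg = 3.0, wh_min = 20),
                       pattern_strength = 2),
    Tro = habitat_spec("Tro", 0.072, "localized_north",
                       beta = c(sst_avg = -1.0, wh_avg = 3.0,
                                geologysedimentary = 1.0),
                       pattern_strength = 2.5),
    Neo = habitat_spec("Neo", 0.0328, "localized_south",
                       beta = c(sst_avg = 1.0, wh_avg = -2.5, wh_min = -15),
                       pattern_strength = 2.5),
    Hph = habitat_spec("Hph", 0.0074, "rare_scattered",
                       beta = c(sst_avg = -0.8, wh_avg = 1.5),
                       pattern_strength = 0),
    Cme = habitat_spec("Cme", 0.284, "widespread",
                       beta = c(sst_avg = -0.6, wh_avg = 2.0, wh_min = 10,
                                substrateartificial = -1.5),
                       pattern_strength = 0)
  )
}

# Stationary unit-variance AR(1) series.
ar1_series <- function(n, rho) {
  eps <- stats::rnorm(n)
  if (rho == 0) return(eps)
  x <- numeric(n)
  x[1] <- eps[1]
  s <- sqrt(1 - rho^2)
  for (i in 2:n) x[i] <- rho * x[i - 1] + s * eps[i]
  x
}

rescale_range <- function(z, range) {
  zr <- range(z)
  if (diff(zr) == 0) return(rep(mean(range), length(z)))
  (z - zr[1]) / diff(zr) * diff(range) + range[1]
}

# First-order Markov categorical sequence with geometric run lengths.
markov_sequence <- function(n, levels, segment_length) {
  switch_p <- 1 / segment_length
  out <- character(n)
  out[1] <- sample(levels, 1L)
  if (length(levels) == 1L) return(rep(levels, n))
  sw <- stats::runif(n) < switch_p
  for (i in 2:n) {
    out[i] <- if (sw[i]) sample(setdiff(levels, out[i - 1]), 1L) else out[i - 1]
  }
  out
}

#' Generate a synthetic coastal environment
#'
#' Lays `n` points on a gently curved southward chain with fixed spacing and
#' simulates the environmental predictors: SST as a linear north-to-south
#' warming gradient spanning `sst_range` plus AR(1) noise (clipped to the
#' range); mean and minimum wave height as AR(1) processes rescaled into
#' their ranges with `wh_min <= wh_avg` enforced pointwise; slope class,
#' geology and substrate as first-order Markov chains with geometric run
#' lengths. Habitat layers are added separately ([generate_habitat()]).
#'
#' @param config a [coast_config].
#' @return a [coastline] with empty habitat set.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "coast_config"))
  n <- config$n
  with_seed(config$seed, {
    # coordinates: heading wanders gently around due south
    t_ <- seq_len(n) / n
    theta <- -pi / 2 + 0.35 * sin(2 * pi * 3 * t_)
    x <- cumsum(config$spacing * cos(theta))
    y <- cumsum(config$spacing * sin(theta))
    x <- x - x[1]
    y <- y - y[1]  # starts at 0, decreases southward: point 1 is northernmost

    sst <- seq(config$sst_range[1], config$sst_range[2], length.out = n) +
      config$sst_noise_sd * ar1_series(n, config$ar_rho)
    sst <- pmin(pmax(sst, config$sst_range[1]), config$sst_range[2])

    wh_avg <- rescale_range(ar1_series(n, config$ar_rho), config$wh_avg_range)
    wh_min <- rescale_range(ar1_series(n, config$ar_rho), config$wh_min_range)
    wh_min <- pmin(wh_min, wh_avg)

    slope <- markov_sequence(n, as.character(1:5), config$segment_length)
    geology <- markov_sequence(
      n, c("metamorphic", "mineral", "plutonic", "sedimentary", "artificial"),
      config$segment_length)
    substrate <- markov_sequence(n, c("natural", "artificial"),
                                 config$segment_length)

    coastline(data.frame(
      x = x, y = y, sst_avg = sst, wh_avg = wh_avg, wh_min = wh_min,
      slope_class = as.integer(slope), geology = geology,
      substrate = substrate, stringsAsFactors = FALSE
    ), habitat_codes = character(0), check_chain = FALSE)
  })
}

# Generator design: dummy coding against the pinned references, with
# continuous columns centered at their coastline means so the calibrated
# intercept stays within a bounded search window.
generator_design <- function(env) {
  design <- build_design(env, candidate_terms(), ref = generator_refs())
  for (cn in intersect(colnames(design$X), continuous_terms())) {
    design$X[, cn] <- design$X[, cn] - mean(design$X[, cn])
  }
  design
}

# Logit-scale linear predictor of a habitat spec (no intercept): X beta plus
# the pattern offset. rare_scattered shrinks beta by 0.25.
habitat_linpred <- function(env, spec) {
  n <- nrow(env)
  beta <- spec$beta
  if (spec$pattern == "rare_scattered") beta <- beta * 0.25
  design <- generator_design(env)
  X <- design$X
  unknown <- setdiff(names(beta), colnames(X))
  if (length(unknown) > 0L) {
    stop("habitat_spec beta names not in design: ",
         paste(unknown, collapse = ", "))
  }
  eta <- drop(X[, names(beta), drop = FALSE] %*% beta)
  north <- env$index < floor(n / 2)
  offset <- switch(spec$pattern,
    widespread = 0,
    rare_scattered = 0,
    localized_north = spec$pattern_strength * ifelse(north, 1, -1),
    localized_south = spec$pattern_strength * ifelse(north, -1, 1))
  eta + offset
}

#' Calibrate a habitat intercept to a target prevalence
#'
#' Finds, by bisection over `[-20, 20]`, the intercept for which the mean
#' occurrence probability `mean(plogis(intercept + eta))` over the coastline
#' is within 0.002 of the spec's target prevalence. The mean probability is
#' monotone in the intercept, so bisection is exact up to tolerance. If even
#' the interval endpoints cannot bracket the target (a pattern zone too small
#' for the requested prevalence), an error reports the achievable range.
#'
#' @param env a [coastline] with environmental columns.
#' @param spec a [habitat_spec].
#' @param tol prevalence tolerance (default 0.002).
#' @return intercept in logit units.
#' @export
calibrate_intercept <- function(env, spec, tol = 0.002) {
  eta <- habitat_linpred(env, spec)
  mean_p <- function(b0) mean(stats::plogis(b0 + eta))
  lo <- -20; hi <- 20
  p_lo <- mean_p(lo); p_hi <- mean_p(hi)
  if (spec$target_prevalence < p_lo || spec$target_prevalence > p_hi) {
    stop(sprintf(
      "target prevalence %.4f unreachable; achievable range [%.4f, %.4f]",
      spec$target_prevalence, p_lo, p_hi))
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pm <- mean_p(mid)
    if (abs(pm - spec$target_prevalence) <= tol) return(mid)
    if (pm < spec$target_prevalence) lo <- mid else hi <- mid
  }
  stop("intercept calibration did not converge")  # not reachable in practice
}

#' Add a Bernoulli habitat layer to a synthetic environment
#'
#' Draws each point's presence from
#' `Bernoulli(plogis(intercept + X beta + pattern offset))` with the
#' calibrated intercept, and appends the 0/1 column to the dataset.
#'
#' @param env a [coastline].
#' @param spec a [habitat_spec].
#' @param seed integer seed for the Bernoulli draws.
#' @return the [coastline] with the habitat column added.
#' @export
generate_habitat <- function(env, spec, seed = 1L) {
  eta <- habitat_linpred(env, spec)
  b0 <- calibrate_intercept(env, spec)
  p <- stats::plogis(b0 + eta)
  yvec <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  out <- as.data.frame(env)
  out[[spec$code]] <- as.integer(yvec)
  coastline(out, habitat_codes = union(habitat_codes(env), spec$code),
            check_chain = FALSE)
}

#' True generating model of a synthetic habitat
#'
#' Returns the exact logistic model a habitat layer was drawn from: the
#' design matrix (the beta-weighted environmental columns plus, for localized
#' patterns, a northern-half indicator) and the true coefficient vector on
#' that design. Useful for parameter-recovery checks: refitting this design
#' on the generated 0/1 layer should recover every coefficient within
#' estimation error.
#'
#' @param env a [coastline] with environmental columns.
#' @param spec the [habitat_spec] used to generate the layer.
#' @return list with `design` (a [build_design()]-style list; continuous
#'   columns centered as in the generator) and `beta_true` (named vector
#'   incl. `(Intercept)`).
#' @export
generating_model <- function(env, spec) {
  eta_beta <- spec$beta
  if (spec$pattern == "rare_scattered") eta_beta <- eta_beta * 0.25
  full <- generator_design(env)
  X <- cbind(`(Intercept)` = 1, full$X[, names(eta_beta), drop = FALSE])
  b0 <- calibrate_intercept(env, spec)
  beta_true <- c(`(Intercept)` = b0, eta_beta)
  if (spec$pattern %in% c("localized_north", "localized_south")) {
    n <- nrow(env)
    north <- as.numeric(env$index < floor(n / 2))
    zone <- if (spec$pattern == "localized_north") north else 1 - north
    # offset s*(2*zone - 1) = 2s*zone - s
    X <- cbind(X, zone = zone)
    beta_true["(Intercept)"] <- b0 - spec$pattern_strength
    beta_true <- c(beta_true, zone = 2 * spec$pattern_strength)
  }
  ct <- colnames(X); names(ct) <- colnames(X)
  list(design = list(X = X, terms = character(0), col_terms = ct,
                     ref_levels = character(0), levels = list()),
       beta_true = beta_true)
}

#' Simulate a complete synthetic coastline
#'
#' Generates the environment and all requested habitat layers. Habitat draws
#' use seeds derived from the config seed (`seed + layer position`), so the
#' whole world is reproducible from the config alone.
#'
#' @param config a [coast_config].
#' @param specs list of [habitat_spec] objects (default
#'   [default_habitat_specs()]).
#' @return a [coastline] with all habitat layers.
#' @export
simulate_coastline <- function(config = coast_config(),
                               specs = default_habitat_specs()) {
  env <- generate_environment(config)
  for (i in seq_along(specs)) {
    env <- generate_habitat(env, specs[[i]], seed = config$seed + i)
  }
  env
}
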