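test_that("intercept-only fit recovers logit of the prevalence", {
  y <- c(rep(1, 30), rep(0, 70))
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coef[1]), stats::qlogis(0.3), tolerance = 1e-6)
  expect_equal(fit$d2, 0, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("a single binary predictor gives the 2x2 log odds ratio", {
  # a,b: presence/absence on artificial; c,d: on natural
  a <- 20; b <- 10; c_ <- 5; d <- 40
  df <- tiny_coast_df(a + b + c_ + d)
  df$substrate <- c(rep("artificial", a + b), rep("natural", c_ + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
  design <- build_design(df, "substrate", ref = list(substrate = "natural"))
  fit <- fit_logistic(design, y)
  expect_equal(unname(fit$coef["substrateartificial"]),
               log(a * d / (b * c_)), tolerance = 1e-6)
  expect_equal(unname(fit$coef["(Intercept)"]), log(c_ / d),
               tolerance = 1e-6)
})

test_that("IRLS matches the stats::glm maximum-likelihood oracle", {
  set.seed(77)
  max_diff <- 0
  for (r in 1:20) {
    n <- 60
    df <- tiny_coast_df(n)
    df$sst_avg <- rnorm(n)
    df$wh_avg <- rnorm(n)
    df$substrate <- sample(c("natural", "artificial"), n, replace = TRUE)
    eta <- 0.3 - 0.8 * df$sst_avg + 0.5 * df$wh_avg
    y <- rbinom(n, 1, plogis(eta))
    if (all(y == 0) || all(y == 1)) next
    design <- build_design(df, c("sst_avg", "wh_avg", "substrate"),
                           ref = list(substrate = "natural"))
    fit <- fit_logistic(design, y)
    oracle <- suppressWarnings(
      stats::glm.fit(design$X, y, family = stats::binomial()))
    max_diff <- max(max_diff,
                    max(abs(fit$coef - oracle$coefficients)))
    expect_equal(fit$residual_deviance, oracle$deviance, tolerance = 1e-6)
    expect_equal(fit$aic, oracle$deviance + 2 * ncol(design$X),
                 tolerance = 1e-6)
  }
  expect_lt(max_diff, 1e-4)
})

test_that("estimates on model-generated data fall within 3 SE of truth", {
  cs <- small_world(n = 16098, seed = 31, prevalence = 0.4,
                    beta = c(sst_avg = -1, wh_avg = 2))
  spec <- habitat_spec("H", 0.4, "widespread",
                       beta = c(sst_avg = -1, wh_avg = 2))
  env <- generate_environment(coast_config(n = 16098, seed = 31))
  gm <- generating_model(env, spec)
  fit <- fit_logistic(gm$design, cs$H)
  oracle <- suppressWarnings(
    stats::glm.fit(gm$design$X, cs$H, family = stats::binomial()))
  se <- sqrt(diag(chol2inv(chol(
    crossprod(gm$design$X * oracle$weights, gm$design$X)))))
  expect_true(all(abs(fit$coef - gm$beta_true) <= 3 * se))
})

test_that("degenerate and rank-deficient inputs are handled as specified", {
  X <- matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)"))
  expect_error(fit_logistic(X, rep(0, 20)), class = "hdm_degenerate_error")
  expect_error(fit_logistic(X, rep(1, 20)), class = "hdm_degenerate_error")

  set.seed(5)
  x <- rnorm(50)
  Xr <- cbind(`(Intercept)` = 1, a = x, b = x)
  y <- rbinom(50, 1, plogis(x))
  if (all(y == 0)) y[1] <- 1
  if (all(y == 1)) y[1] <- 0
  expect_warning(fit <- fit_logistic(Xr, y), "aliased")
  expect_length(fit$coef, 2)
})

test_that("separation is flagged, not fatal", {
  df <- tiny_coast_df(40)
  df$sst_avg <- c(rnorm(20, -3), rnorm(20, 3))
  y <- c(rep(0, 20), rep(1, 20))
  design <- build_design(df, "sst_avg")
  fit <- fit_logistic(design, y)
  expect_true(fit$separation_flag)
  expect_true(is.finite(fit$aic))
})

test_that("mean fitted probability equals training prevalence", {
  cs <- small_world(n = 1000, seed = 41)
  design <- build_design(cs, candidate_terms())
  fit <- fit_logistic(design, cs$H)
  expect_equal(mean(predict_prob(fit, cs)), mean(cs$H), tolerance = 1e-6)
})

test_that("AIC selection enumerates all subsets and beats the endpoints", {
  cs <- small_world(n = 1000, seed = 43)
  sel2 <- select_model_aic(cs, cs$H, candidates = c("sst_avg", "wh_avg"))
  expect_identical(sel2$n_models, 4L)

  sel <- select_model_aic(cs, cs$H)
  expect_identical(sel$n_models, 64L)
  full <- fit_logistic(build_design(cs, candidate_terms()), cs$H)
  null <- fit_logistic(build_design(cs, character(0)), cs$H)
  expect_lte(sel$aic, full$aic + 1e-8)
  expect_lte(sel$aic, null$aic + 1e-8)
  expect_gte(sel$d2, 0)
  expect_lte(sel$d2, full$d2 + 1e-8)
  expect_error(select_model_aic(cs, rep(1, nrow(cs))),
               class = "hdm_degenerate_error")
})

test_that("selection finds the true predictor and rejects pure noise", {
  # the true predictor must always enter; AIC is expected to admit each
  # irrelevant term in ~16% of replicates (P[chisq_1 > 2]), so the exact
  # singleton set is only required in a clear majority
  true_in <- 0L
  exact <- 0L
  for (r in 1:20) {
    env <- generate_environment(coast_config(n = 5000, seed = 600 + r))
    spec <- habitat_spec("H", 0.4, "widespread", beta = c(sst_avg = -3))
    hab <- generate_habitat(env, spec, seed = 700 + r)
    sel <- select_model_aic(hab, hab$H,
                            candidates = c("sst_avg", "wh_avg", "wh_min"))
    if ("sst_avg" %in% sel$selected) true_in <- true_in + 1L
    if (identical(sel$selected, "sst_avg")) exact <- exact + 1L
  }
  expect_identical(true_in, 20L)
  expect_gte(exact, 11L)

  nulls <- 0L
  for (r in 1:20) {
    env <- generate_environment(coast_config(n = 2000, seed = 800 + r))
    set.seed(900 + r)
    y <- rbinom(2000, 1, 0.3)
    sel <- select_model_aic(env, y,
                            candidates = c("sst_avg", "wh_avg", "wh_min"))
    if (length(sel$selected) == 0L) nulls <- nulls + 1L
  }
  expect_gt(nulls, 10L)
})

test_that("explained deviance follows the printed formula", {
  expect_equal(explained_deviance(138.6, 103.95), 25.0)
  expect_error(explained_deviance(0, 0), "zero")
})

test_that("predictions are inverse-logit, clipped, and column-checked", {
  cs <- small_world(n = 300, seed = 47)
  design <- build_design(cs, c("sst_avg", "substrate"))
  fit <- fit_logistic(design, cs$H)

  # zero coefficients -> 0.5 everywhere
  fit0 <- fit
  fit0$coef[] <- 0
  expect_equal(predict_prob(fit0, cs), rep(0.5, 300))

  # huge linear predictor saturates but never reaches 1
  fit1 <- fit
  fit1$coef[] <- 0
  fit1$coef["(Intercept)"] <- 40
  p <- predict_prob(fit1, cs)
  expect_true(all(p >= 1 - 1e-6) && all(p < 1))

  expect_error(predict_prob(fit, cs[, setdiff(names(cs), "substrate")]),
               "substrate")

  # unseen categorical level maps to the reference with a warning
  newd <- as.data.frame(cs[1:5, ])
  newd$substrate <- "weird"
  ref_d <- as.data.frame(cs[1:5, ])
  ref_d$substrate <- fit$ref_levels[["substrate"]]
  expect_warning(p_new <- predict_prob(fit, newd), "unseen")
  expect_equal(p_new, predict_prob(fit, ref_d))
})
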