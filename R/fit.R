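#' Candidate environmental predictor terms
#'
#' The six predictor terms available to the habitat models: mean sea-surface
#' temperature, mean and minimum wave height (continuous), and slope class,
#' geology and substrate type (categorical, entering the model as whole dummy
#' blocks).
#'
#' @return character vector of term names.
#' @export
candidate_terms <- function() {
  c("sst_avg", "wh_avg", "wh_min", "slope_class", "geology", "substrate")
}

continuous_terms <- function() c("sst_avg", "wh_avg", "wh_min")

#' Build a dummy-coded design matrix
#'
#' Expands the requested predictor terms into an intercept-first numeric
#' design matrix. Continuous terms enter as-is; categorical terms are
#' treatment (dummy) coded against a reference level. By default the
#' reference is the most frequent level in `data` (which stabilizes fits on
#' small or unbalanced training samples); fixed references can be supplied.
#' Levels absent from `data` produce no column.
#'
#' @param data data.frame (typically a [coastline] or a training subset).
#' @param terms character vector of term names from [candidate_terms()].
#' @param ref `NULL` (most frequent level per categorical term) or a named
#'   list/character vector of reference levels, e.g.
#'   `list(slope_class = "1", geology = "metamorphic")`.
#' @return list with `X` (matrix incl. `(Intercept)` column), `terms`,
#'   `col_terms` (term of each column), `ref_levels` (named character), and
#'   `levels` (observed level sets per categorical term).
#' @export
build_design <- function(data, terms = candidate_terms(), ref = NULL) {
  stopifnot(all(terms %in% candidate_terms()))
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  col_terms <- c("(Intercept)" = "(Intercept)")
  ref_levels <- character(0)
  level_sets <- list()
  for (tm in terms) {
    if (tm %in% continuous_terms()) {
      cols[[tm]] <- as.numeric(data[[tm]])
      col_terms[tm] <- tm
    } else {
      v <- as.character(data[[tm]])
      tab <- table(v)
      levs <- names(tab)
      r <- if (!is.null(ref) && !is.null(ref[[tm]])) {
        as.character(ref[[tm]])
      } else {
        names(tab)[which.max(tab)]  # most frequent; first alphabetically on tie
      }
      if (!r %in% levs) r <- names(tab)[which.max(tab)]
      level_sets[[tm]] <- c(r, setdiff(levs, r))
      ref_levels[tm] <- r
      for (lv in setdiff(levs, r)) {
        nm <- paste0(tm, lv)
        cols[[nm]] <- as.numeric(v == lv)
        col_terms[nm] <- tm
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, terms = terms, col_terms = col_terms,
       ref_levels = ref_levels, levels = level_sets)
}

# Binomial deviance for 0/1 data: -2 * log-likelihood (saturated ll = 0).
binomial_deviance <- function(y, mu) {
  mu <- clip_prob(mu)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Fit a binomial logistic model by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, stopping when the deviance changes by less than `tol` or after
#' `max_iter` iterations. A small ridge term (`1e-8`) on the normal equations
#' keeps the solve stable under quasi-complete separation, which occurs
#' routinely when rare habitats are fitted on small training stretches; such
#' fits are flagged (`separation_flag`) rather than failed: any coefficient
#' exceeding 15 in absolute value after internally standardizing continuous
#' columns trips the flag. Aliased (rank-deficient) columns are dropped with
#' a warning.
#'
#' @param design a design list from [build_design()], or a numeric matrix
#'   whose first column is the intercept.
#' @param y 0/1 response vector, one per design row.
#' @param tol deviance-change convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return an object of class `hdm_fit`: coefficients (logit scale), null and
#'   residual deviance, AIC (`deviance + 2 * n_coef`), explained deviance
#'   `d2` in percent, convergence and separation flags, and the design
#'   metadata needed for prediction.
#' @export
fit_logistic <- function(design, y, tol = 1e-8, max_iter = 50L) {
  if (is.matrix(design)) design <- list(X = design, terms = character(0),
                                        col_terms = NULL, ref_levels = character(0),
                                        levels = list())
  X <- design$X
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (all(y == 0) || all(y == 1)) {
    stop_degenerate(sprintf(
      "degenerate training sample: response is all %d", y[1L]))
  }

  # drop aliased columns
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping aliased column(s): ", paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }

  p <- ncol(X)
  beta <- numeric(p)
  dev <- binomial_deviance(y, rep(0.5, length(y)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- clip_prob(stats::plogis(eta), 1e-10)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    A <- XtW %*% X + diag(1e-8, p)
    beta_new <- drop(solve(A, XtW %*% z))
    dev_new <- binomial_deviance(y, stats::plogis(drop(X %*% beta_new)))
    beta <- beta_new
    if (abs(dev - dev_new) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  names(beta) <- colnames(X)

  pbar <- mean(y)
  null_dev <- binomial_deviance(y, rep(pbar, length(y)))

  # separation check on an internally standardized scale
  sds <- vapply(seq_len(p), function(j) {
    cn <- colnames(X)[j]
    if (cn %in% continuous_terms()) stats::sd(X[, j]) else 1
  }, numeric(1))
  separation_flag <- any(abs(beta * sds)[-1] > 15) ||
    (p == 1 && abs(beta[1]) > 15)

  structure(list(
    coef = beta,
    terms = design$terms,
    col_terms = design$col_terms,
    ref_levels = design$ref_levels,
    levels = design$levels,
    null_deviance = null_dev,
    residual_deviance = dev,
    aic = dev + 2 * p,
    d2 = (null_dev - dev) / null_dev * 100,
    n = length(y),
    prevalence = pbar,
    converged = converged,
    separation_flag = separation_flag
  ), class = "hdm_fit")
}

#' @export
print.hdm_fit <- function(x, ...) {
  cat(sprintf("<hdm_fit> terms: %s\n",
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)"))
  cat(sprintf("  n = %d, prevalence = %.4f\n", x$n, x$prevalence))
  cat(sprintf("  deviance %.2f (null %.2f), AIC %.2f, D2 = %.2f%%\n",
              x$residual_deviance, x$null_deviance, x$aic, x$d2))
  if (x$separation_flag) cat("  note: separation flag set\n")
  invisible(x)
}

#' Exhaustive AIC best-subset selection for a habitat model
#'
#' Fits every subset of the candidate predictor terms (categorical predictors
#' enter or leave as whole dummy blocks, so 6 candidates means 64 fits) and
#' returns the fit with the smallest AIC. Ties are broken in favour of fewer
#' terms, then lexicographic term order. This mirrors AIC-driven automated
#' model selection over a main-effects candidate set.
#'
#' @param data data.frame holding the predictor columns (training rows).
#' @param y 0/1 response aligned to `data` rows.
#' @param candidates candidate term names (at most 12).
#' @param ref reference-level override passed to [build_design()].
#' @return the best `hdm_fit`, with `$selected` (character vector of selected
#'   terms) and `$n_models` (number of subsets fitted).
#' @export
select_model_aic <- function(data, y, candidates = candidate_terms(),
                             ref = NULL) {
  stopifnot(length(candidates) <= 12)
  if (all(y == 0) || all(y == 1)) {
    stop_degenerate("degenerate training sample: constant response")
  }
  full <- build_design(data, candidates, ref = ref)
  k <- length(candidates)
  best <- NULL
  best_key <- NULL
  n_models <- 0L
  for (mask in 0:(2^k - 1)) {
    sel <- candidates[bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L) == 1L]
    keep <- full$col_terms %in% c("(Intercept)", sel)
    sub <- list(X = full$X[, keep, drop = FALSE],
                terms = sel,
                col_terms = full$col_terms[keep],
                ref_levels = full$ref_levels[names(full$ref_levels) %in% sel],
                levels = full$levels[names(full$levels) %in% sel])
    fit <- suppressWarnings(fit_logistic(sub, y))
    n_models <- n_models + 1L
    key <- list(fit$aic, length(sel), paste(sort(sel), collapse = "+"))
    if (is.null(best) ||
        key[[1]] < best_key[[1]] - 1e-10 ||
        (abs(key[[1]] - best_key[[1]]) <= 1e-10 &&
         (key[[2]] < best_key[[2]] ||
          (key[[2]] == best_key[[2]] && key[[3]] < best_key[[3]])))) {
      best <- fit
      best_key <- key
    }
  }
  best$selected <- best$terms
  best$n_models <- n_models
  best
}

#' Explained deviance of a fitted model
#'
#' The GLM analog of R-squared:
#' `(null deviance - residual deviance) / null deviance x 100`.
#'
#' @param fit an `hdm_fit`, or a null deviance (with `residual` given).
#' @param residual residual deviance when `fit` is numeric.
#' @return percent of null deviance explained.
#' @export
explained_deviance <- function(fit, residual = NULL) {
  if (inherits(fit, "hdm_fit")) {
    null_dev <- fit$null_deviance
    residual <- fit$residual_deviance
  } else {
    null_dev <- fit
  }
  if (null_dev <= 0) stop("null deviance is zero: constant response")
  (null_dev - residual) / null_dev * 100
}

#' Predict occurrence probabilities from a fitted habitat model
#'
#' Applies the fitted logit-scale coefficients to new data, rebuilding the
#' dummy coding used in training (same reference levels). Categorical levels
#' unseen in training are mapped to the reference level with a warning.
#' Outputs are clipped into the open interval (0, 1).
#'
#' @param fit an `hdm_fit`.
#' @param newdata data.frame with the predictor columns used by `fit`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(fit, newdata) {
  stopifnot(inherits(fit, "hdm_fit"))
  missing_cols <- setdiff(fit$terms, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata missing term column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(newdata)
  eta <- rep(fit$coef[["(Intercept)"]], n)
  for (j in seq_along(fit$coef)) {
    cn <- names(fit$coef)[j]
    if (cn == "(Intercept)") next
    tm <- fit$col_terms[[cn]]
    if (tm %in% continuous_terms()) {
      eta <- eta + fit$coef[j] * as.numeric(newdata[[tm]])
    } else {
      lv <- substring(cn, nchar(tm) + 1L)
      v <- as.character(newdata[[tm]])
      unseen <- !(v %in% fit$levels[[tm]])
      if (any(unseen)) {
        warning(sprintf(
          "%d value(s) of '%s' at unseen level(s) mapped to reference '%s'",
          sum(unseen), tm, fit$ref_levels[[tm]]))
      }
      eta <- eta + fit$coef[j] * as.numeric(v == lv)
    }
  }
  clip_prob(stats::plogis(eta))
}
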