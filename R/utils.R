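# Internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

logit <- function(p) log(p / (1 - p))

# Clip probabilities into the open unit interval.
clip_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("hdm_degenerate_error", "error")))
}

is_degenerate_error <- function(e) inherits(e, "hdm_degenerate_error")
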