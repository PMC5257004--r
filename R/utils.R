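# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper)
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

# log-normal with a given arithmetic mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

qlnorm_mean_cv <- function(p, mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::qlnorm(p, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
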