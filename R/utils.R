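# Internal helpers: argument checks, seeded sub-streams, lognormal
# parameterization by mean and coefficient of variation.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("metaburden_domain_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("metaburden_input_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_domain(name, " must be > ", lower, " (got ", x, ")")
  if (!strict_lower && x < lower)
    stop_domain(name, " must be >= ", lower, " (got ", x, ")")
  if (x > upper)
    stop_domain(name, " must be <= ", upper, " (got ", x, ")")
  invisible(x)
}

# Deterministic sub-stream derivation: a single user seed is split
# hierarchically (clone -> mouse -> colony/week) by folding integer indices
# into a 31-bit linear-congruential hash. The scheme is part of the
# reproducibility contract and must not change between versions.
MOD31 <- 2147483647

child_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.numeric(seed) %% MOD31
  for (i in idx) {
    i <- if (is.character(i)) sum(utf8ToInt(i) * seq_along(utf8ToInt(i))) else as.numeric(i)
    x <- (x * 69069 + i * 1234567 + 987654321) %% MOD31
  }
  as.integer(x)
}

# Lognormal with prescribed arithmetic mean and coefficient of variation.
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_mcv <- function(n, mean, cv) {
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep(mean, n))
  p <- lnorm_pars(mean, cv)
  stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
}
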