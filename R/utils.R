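# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic substream seed derived from a master seed. Kept below 2^31.
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + index * 16807) %% 2147483647)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("'%s' must be a finite numeric scalar", name)
  }
  if (x < lower || x > upper) {
    stop_validation("'%s' = %g outside allowed range [%g, %g]",
                    name, x, lower, upper)
  }
  invisible(x)
}

# Variance of a standard normal truncated to [-a, a].
truncnorm_sym_var <- function(a) {
  z <- 2 * stats::pnorm(a) - 1
  1 - 2 * a * stats::dnorm(a) / z
}

# Draw from a standard normal truncated to [-a, a], rescaled to unit variance.
rtrunc_std <- function(n, a = 2.2) {
  u <- stats::qnorm(stats::pnorm(-a) +
                      stats::runif(n) * (stats::pnorm(a) - stats::pnorm(-a)))
  u / sqrt(truncnorm_sym_var(a))
}
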