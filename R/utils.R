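# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic package code (pruning, bootstrap, perturbation, simulation)
# funnels through here so that results are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Two-sided normal p-value for estimate/se.
normal_p <- function(estimate, se) 2 * stats::pnorm(-abs(estimate / se))

# Normal-quantile confidence limits.
normal_ci <- function(estimate, se, level = 0.95) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = estimate - q * se, upper = estimate + q * se)
}

# Solve A x = b for symmetric positive-definite A via Cholesky.
chol_solve <- function(A, b) {
  U <- chol(A)
  backsolve(U, forwardsolve(t(U), b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
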