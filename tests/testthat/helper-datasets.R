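# Shared test helpers: small random datasets and correlation matrices built
# in code (no stored fixtures beyond the in-package worked example).

random_pd_corr <- function(J, seed) {
  with_seed_local(seed, {
    A <- matrix(stats::rnorm(J * J), J)
    S <- crossprod(A) + J * diag(J)
    stats::cov2cor(S)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Empirical correlation matrix from simulated allele-count-like data, with
# optional near-duplicate pairs (always PSD by construction). `dups` is a
# list of c(source, target, noise_sd) triples.
empirical_corr <- function(J, seed, dups = list(), n = 500) {
  with_seed_local(seed, {
    X <- matrix(stats::rnorm(n * J), n, J)
    for (d in dups) {
      sgn <- if (length(d) >= 4 && d[4] < 0) -1 else 1
      X[, d[2]] <- sgn * X[, d[1]] + d[3] * stats::rnorm(n)
    }
    m <- stats::cor(X)
    dimnames(m) <- list(paste0("snp_", seq_len(J)), paste0("snp_", seq_len(J)))
    m
  })
}

random_dataset <- function(J, seed, correlated = FALSE) {
  rho <- if (correlated) random_pd_corr(J, seed + 1000L) else NULL
  sim <- simulate_univariable(J = J, theta = 0.3, strength = "strong",
                              rho = rho, seed = seed)
  sim$dataset
}

# Flip variant j's orientation in a univariable dataset (bx, by signs and the
# correlation row/column), as under allele recoding.
recode_variant <- function(data, j) {
  data$bx[j] <- -data$bx[j]
  data$by[j] <- -data$by[j]
  if (!is.null(data$correlation)) {
    f <- rep(1, length(data$bx)); f[j] <- -1
    data$correlation <- data$correlation * (f %o% f)
  }
  data
}

recode_variant_mv <- function(data, j) {
  data$BX[j, ] <- -data$BX[j, ]
  data$by[j] <- -data$by[j]
  if (!is.null(data$correlation)) {
    f <- rep(1, nrow(data$BX)); f[j] <- -1
    data$correlation <- data$correlation * (f %o% f)
  }
  data
}
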