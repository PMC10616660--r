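test_that("sign-flip harmonization reproduces the worked-example matrix", {
  fx <- casr_fixtures()
  out <- flip_correlation(fx$rho, fx$flip)
  expect_equal(out, fx$rho_signed)
  expect_equal(out[1, 3], -0.094)   # single flip changes the sign
  expect_equal(out[3, 5], 0.349)    # double flip cancels
  expect_equal(diag(out), diag(fx$rho))
})

test_that("flip is an identity for all +1 and an involution, preserving eigenvalues", {
  fx <- casr_fixtures()
  expect_equal(flip_correlation(fx$rho, rep(1, 6)), fx$rho)
  for (seed in 1:5) {
    rho <- random_pd_corr(6, seed)
    flip <- with_seed_local(seed, sample(c(-1, 1), 6, replace = TRUE))
    once <- flip_correlation(rho, flip)
    expect_equal(flip_correlation(once, flip), rho)
    expect_equal(eigen(once, symmetric = TRUE, only.values = TRUE)$values,
                 eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  }
  expect_error(flip_correlation(fx$rho, c(1, 1, 0, 1, 1, 1)), "\\+1 or -1")
  expect_error(flip_correlation(fx$rho, c(1, 1)), "length")
})

test_that("pruning removes nothing below threshold and one of a forced pair", {
  rho <- random_pd_corr(5, 1)
  rho[abs(rho) > 0.9 & row(rho) != col(rho)] <- 0.5  # cap off-diagonals
  rho <- validate_correlation(stats::cov2cor(rho), warn_unsigned = FALSE)
  pr <- prune_by_r2(rho, 0.95)
  expect_length(pr$omitted, 0L)
  expect_length(pr$kept, 5L)

  pair <- matrix(c(1, 0.99, 0.99, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pr2 <- prune_by_r2(pair, 0.95, seed = 1)
  expect_length(pr2$omitted, 1L)
  expect_length(pr2$kept, 1L)
})

test_that("three pairwise near-duplicates leave exactly one variant", {
  rho <- matrix(0.99, 3, 3); diag(rho) <- 1
  dimnames(rho) <- list(paste0("v", 1:3), paste0("v", 1:3))
  pr <- prune_by_r2(rho, 0.95, seed = 7)
  expect_length(pr$omitted, 2L)
  expect_length(pr$kept, 1L)
})

test_that("pruning is deterministic given a seed and idempotent on the kept set", {
  for (seed in c(496, 1, 99)) {
    # empirical matrix with one near-duplicate pair and one negated pair
    rho <- empirical_corr(12, seed + 3,
                          dups = list(c(1, 2, 0.05), c(3, 4, 0.05, -1)))
    a <- prune_by_r2(rho, 0.95, seed = seed)
    b <- prune_by_r2(rho, 0.95, seed = seed)
    expect_identical(a$omitted, b$omitted)
    # post-condition: no surviving pair exceeds the threshold
    kept <- rho[a$kept, a$kept, drop = FALSE]
    off <- kept[upper.tri(kept)]
    expect_true(all(off^2 <= 0.95))
    # idempotence: re-pruning the kept set removes nothing
    again <- prune_by_r2(kept, 0.95, seed = seed)
    expect_length(again$omitted, 0L)
  }
})

test_that("a stricter r-squared threshold never keeps more variants", {
  for (seed in 1:4) {
    rho <- empirical_corr(10, seed,
                          dups = list(c(1, 2, 0.15), c(2, 3, 0.4)))
    kept_loose <- length(prune_by_r2(rho, 0.95, seed = seed)$kept)
    kept_strict <- length(prune_by_r2(rho, 0.5, seed = seed)$kept)
    expect_lte(kept_strict, kept_loose)
  }
  expect_error(prune_by_r2(diag(2), r2_threshold = 0), "0, 1")
  expect_error(prune_by_r2(diag(2), r2_threshold = 1.2), "0, 1")
})

test_that("Cholesky decorrelation matches its closed forms and quadratic identity", {
  z <- c(1.3, -0.4, 2.2)
  expect_equal(cholesky_decorrelate(z, diag(3)), z)
  # 2x2 closed form
  r <- 0.6
  rho2 <- matrix(c(1, r, r, 1), 2)
  z2 <- c(1.5, -0.7)
  expect_equal(cholesky_decorrelate(z2, rho2),
               c(z2[1], (z2[2] - r * z2[1]) / sqrt(1 - r^2)))
  # quadratic-form identity against an explicit inverse, random instances
  for (seed in 1:5) {
    J <- 4 + seed
    rho <- random_pd_corr(J, seed)
    zz <- with_seed_local(seed + 50, stats::rnorm(J))
    zs <- cholesky_decorrelate(zz, rho)
    expect_equal(sum(zs^2), drop(t(zz) %*% solve(rho) %*% zz), tolerance = 1e-10)
  }
})
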