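test_that("the univariable CUE optimum matches a dense grid search", {
  for (seed in c(1, 6)) {
    d <- simulate_univariable(J = 8, theta = 0.4, strength = "moderate",
                              seed = seed)$dataset
    est <- mr_gmm(d, nx = 50000, ny = 50000, opts = gmm_options(robust = FALSE))
    grid <- seq(-2, 2, by = 1e-4)
    # with uncorrelated variants the CUE objective is a ratio sum
    obj <- vapply(grid, function(th)
      sum((d$by - th * d$bx)^2 / (d$byse^2 + th^2 * d$bxse^2)), numeric(1))
    th_grid <- grid[which.min(obj)]
    expect_lt(abs(est$estimate - th_grid), 2e-4)
    # the optimum improves on the IVW starting value
    th_ivw <- mr_ivw(d, model = "fixed")$estimate
    expect_lte(est$objective,
               sum((d$by - th_ivw * d$bx)^2 / (d$byse^2 + th_ivw^2 * d$bxse^2)) + 1e-8)
  }
})

test_that("multivariable CUE-GMM agrees with IVW under strong instruments", {
  sim <- simulate_multivariable(J = 50, theta = c(0.3, -0.2),
                                strength = "strong", seed = 31)
  g <- mr_mvgmm(sim$dataset, nx = 50000, ny = 50000)
  iv <- mr_mvivw(sim$dataset)
  expect_lt(max(abs(g$estimate - iv$estimate) / iv$se), 3)
  expect_lt(max(abs(g$estimate - sim$truth$theta) / g$se), 4)
})

test_that("GMM estimates are scale-equivariant in the outcome", {
  sim <- simulate_multivariable(J = 20, theta = c(0.3, -0.2), seed = 33)
  d <- sim$dataset
  g1 <- mr_mvgmm(d, nx = 50000, ny = 50000)
  d2 <- d; d2$by <- 2.5 * d$by; d2$byse <- 2.5 * d$byse
  g2 <- mr_mvgmm(d2, nx = 50000, ny = 50000)
  expect_equal(g2$estimate, 2.5 * g1$estimate, tolerance = 1e-4)
})

test_that("GMM estimators are allele-recoding invariant", {
  sim <- simulate_univariable(J = 10, theta = 0.3, strength = "strong",
                              rho = random_pd_corr(10, 3), seed = 35)
  d <- sim$dataset
  g0 <- mr_gmm(d, nx = 50000, ny = 50000)
  g1 <- mr_gmm(recode_variant(d, 4), nx = 50000, ny = 50000)
  expect_equal(g1$estimate, g0$estimate, tolerance = 1e-6)
  expect_equal(g1$se, g0$se, tolerance = 1e-6)
})

test_that("the PC transform selects components by cumulative eigenvalue fraction", {
  fx <- casr_fixtures()
  d <- fx$dataset
  # oracle: independent eigendecomposition of the weighted matrix
  w <- abs(d$bx) / d$byse
  Psi <- d$correlation * (w %o% w)
  lam <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
  r_oracle <- which(cumsum(pmax(lam, 0)) / sum(pmax(lam, 0)) >= 0.999)[1]
  pc <- weighted_pc_transform(d, thres = 0.999)
  expect_equal(pc$r, r_oracle)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # explicit r overrides thres; thres = 1 retains everything
  expect_equal(weighted_pc_transform(d, r = 2)$r, 2L)
  expect_equal(weighted_pc_transform(d, thres = 1)$r, 6L)
  expect_error(weighted_pc_transform(d, r = 7), "1..6")
  d_nocorr <- mr_dataset(d$bx, d$bxse, d$by, d$byse)
  expect_error(weighted_pc_transform(d_nocorr), "correlation")
})

test_that("PC-GMM with identity correlation and r = J matches plain CUE-GMM", {
  sim <- simulate_univariable(J = 8, theta = 0.4, strength = "strong", seed = 41)
  d <- sim$dataset
  d_id <- mr_dataset(d$bx, d$bxse, d$by, d$byse, correlation = diag(8))
  a <- mr_pcgmm(d_id, nx = 50000, ny = 50000, r = 8)
  b <- mr_gmm(d, nx = 50000, ny = 50000)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-4)
  expect_equal(a$se, b$se, tolerance = 1e-3)
})

test_that("PC-GMM runs on the calcium worked example and reports r <= 6", {
  fx <- casr_fixtures()
  est <- mr_pcgmm(fx$dataset, nx = fx$nx, ny = fx$ny)
  expect_true(is.finite(est$estimate) && is.finite(est$se))
  expect_lte(est$r, 6L)
  expect_gte(est$r, 1L)
  expect_true(is.finite(est$strength$f_stat))
})

test_that("PC-GMM is insensitive to duplicating a variant at fixed r", {
  fx <- casr_fixtures()
  d <- fx$dataset
  # r must capture the bulk of the weighted spectrum for the retained
  # subspace to be stable under duplication; r = 5 of 6 does
  est0 <- mr_pcgmm(d, nx = fx$nx, ny = fx$ny, r = 5)
  # duplicate variant 1 with near-perfect correlation to the original
  J <- 6
  rho2 <- rbind(cbind(d$correlation, d$correlation[, 1]),
                c(d$correlation[1, ], 1))
  rho2[J + 1, 1] <- rho2[1, J + 1] <- 0.9999
  ids <- c(d$snps, "snp_1b")
  dimnames(rho2) <- list(ids, ids)
  d2 <- mr_dataset(c(d$bx, d$bx[1]), c(d$bxse, d$bxse[1]),
                   c(d$by, d$by[1]), c(d$byse, d$byse[1]),
                   snps = ids, correlation = rho2)
  est1 <- mr_pcgmm(d2, nx = fx$nx, ny = fx$ny, r = 5)
  expect_lt(abs(est1$estimate - est0$estimate) / abs(est0$estimate), 1e-2)
})

test_that("multivariable PC-GMM is consistent with its special cases", {
  sim <- simulate_multivariable(J = 12, theta = c(0.3, -0.2),
                                strength = "strong", seed = 51)
  d <- sim$dataset
  rho_id <- diag(12); dimnames(rho_id) <- list(d$snps, d$snps)
  d_id <- mr_mvdataset(d$BX, d$BXse, d$by, d$byse, snps = d$snps,
                       correlation = rho_id)
  a <- mr_mvpcgmm(d_id, nx = 50000, ny = 50000, r = 12)
  b <- mr_mvgmm(d, nx = 50000, ny = 50000)
  expect_lt(max(abs(a$estimate - b$estimate) / b$se), 3)
  expect_lt(max(abs(a$estimate - sim$truth$theta) / a$se), 4)
  expect_length(a$strength$conditional_f, 2L)
})
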