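test_that("the debiased IVW point estimate instantiates its formula", {
  # single-variant instantiation: (bx*by/byse^2) / ((bx^2-bxse^2)/byse^2)
  d <- mr_dataset(bx = 1, bxse = 0.5, by = 0.4, byse = 0.2)
  est <- mr_divw(d, over_dispersion = FALSE)
  expect_equal(est$estimate, (1 * 0.4) / (1 - 0.25), tolerance = 1e-12)
})

test_that("dIVW reduces to IVW in the bxse -> 0 limit", {
  d <- random_dataset(10, seed = 17)
  d$bxse <- rep(1e-10, 10)
  a <- mr_divw(d, over_dispersion = FALSE)
  b <- mr_ivw(d, model = "fixed")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
})

test_that("dIVW rejects correlated variants and all-weak degenerate input", {
  d <- random_dataset(6, seed = 19, correlated = TRUE)
  expect_error(mr_divw(d), "uncorrelated")
  weak <- mr_dataset(bx = c(0.001, -0.002, 0.001), bxse = c(0.1, 0.1, 0.1),
                     by = c(0.01, 0.02, -0.01), byse = c(0.1, 0.1, 0.1))
  expect_error(mr_divw(weak), "weak")
})

test_that("dIVW is less biased than IVW with many weak instruments", {
  # simulation oracle: J = 100 weak instruments, theta = 0.5, 200 replicates
  theta <- 0.5
  est_ivw <- est_divw <- numeric(200)
  for (b in 1:200) {
    d <- simulate_univariable(J = 100, theta = theta, strength = "weak",
                              seed = 5000 + b)$dataset
    est_ivw[b] <- mr_ivw(d)$estimate
    est_divw[b] <- mr_divw(d, over_dispersion = FALSE)$estimate
  }
  mc_se <- sd(est_divw) / sqrt(200)
  expect_lt(abs(mean(est_divw) - theta), 3 * mc_se)
  expect_lt(abs(mean(est_divw) - theta), abs(mean(est_ivw) - theta))
})

test_that("overdispersion is estimated at zero for strong clean data", {
  d <- simulate_univariable(J = 100, theta = 0.3, strength = "strong",
                            seed = 77)$dataset
  est <- mr_divw(d, over_dispersion = TRUE)
  expect_lt(est$tau2, 1e-5)
})

test_that("pIVW with lambda = 0 equals dIVW", {
  for (seed in c(2, 9)) {
    d <- simulate_univariable(J = 40, theta = 0.4, strength = "moderate",
                              pleiotropy = "balanced", sd_alpha = 0.005,
                              seed = seed)$dataset
    a <- mr_pivw(d, pivw_options(lambda = 0, over_dispersion = TRUE))
    b <- mr_divw(d, over_dispersion = TRUE)
    expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
    expect_equal(a$se, b$se, tolerance = 1e-8)
  }
})

test_that("screening removes exactly the variants above the p-value cutoff", {
  d <- mr_dataset(bx = c(0.3, 0.2, 0.05), bxse = rep(0.05, 3),
                  by = c(0.15, 0.1, 0.02), byse = rep(0.05, 3))
  est <- mr_pivw(d, pivw_options(delta = 1.96,
                                 sel_pval = c(0.001, 0.04, 0.5),
                                 over_dispersion = FALSE))
  expect_equal(est$n_kept, 2L)        # cutoff 2*pnorm(-1.96) ~ 0.0500
  expect_equal(est$kept, c(1L, 2L))
  # delta = 0 keeps all variants
  est0 <- mr_pivw(d, pivw_options(delta = 0, over_dispersion = FALSE))
  expect_equal(est0$n_kept, 3L)
  expect_error(mr_pivw(d, pivw_options(delta = 1)), "sel_pval")
})

test_that("the bootstrap Fieller interval contains the point estimate", {
  for (seed in c(4, 12)) {
    d <- simulate_univariable(J = 30, theta = 0.2, strength = "weak",
                              seed = seed)$dataset
    est <- mr_pivw(d, pivw_options(boot_fieller = TRUE, n_boot = 300,
                                   seed = 100 + seed))
    expect_lt(est$ci_lower, est$estimate)
    expect_gt(est$ci_upper, est$estimate)
    # seeded: rerun reproduces the interval exactly
    est2 <- mr_pivw(d, pivw_options(boot_fieller = TRUE, n_boot = 300,
                                    seed = 100 + seed))
    expect_identical(est$ci_lower, est2$ci_lower)
    expect_identical(est$p_value, est2$p_value)
  }
})
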