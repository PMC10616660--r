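test_that("single-variant IVW is the Wald ratio", {
  d <- mr_dataset(bx = 0.5, bxse = 0.1, by = 0.2, byse = 0.05)
  est <- mr_ivw(d)
  expect_equal(est$estimate, 0.2 / 0.5)
  expect_equal(est$se, 0.05 / 0.5)
  dneg <- mr_dataset(bx = -0.5, bxse = 0.1, by = 0.2, byse = 0.05)
  expect_equal(mr_ivw(dneg)$se, 0.05 / abs(-0.5))
})

test_that("IVW equals the explicit GLS oracle on random correlated instances", {
  for (seed in 1:6) {
    J <- sample(3:10, 1)
    d <- random_dataset(J, seed = seed, correlated = TRUE)
    est <- mr_ivw(d, model = "fixed")
    Omega <- (d$byse %o% d$byse) * d$correlation
    Oi <- solve(Omega)
    x <- d$bx
    oracle <- drop(solve(t(x) %*% Oi %*% x) %*% t(x) %*% Oi %*% d$by)
    expect_equal(est$estimate, oracle, tolerance = 1e-10)
    expect_equal(est$se, sqrt(drop(solve(t(x) %*% Oi %*% x))), tolerance = 1e-10)
  }
})

test_that("identity correlation reproduces the uncorrelated IVW result", {
  d <- random_dataset(9, seed = 21)
  d_id <- d; d_id$correlation <- diag(9)
  a <- mr_ivw(d); b <- mr_ivw(d_id)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("IVW is scale-equivariant and allele-recoding invariant", {
  d <- random_dataset(8, seed = 30, correlated = TRUE)
  est <- mr_ivw(d)
  c_ <- 3.7
  d_sc <- d; d_sc$by <- c_ * d$by; d_sc$byse <- c_ * d$byse
  est_sc <- mr_ivw(d_sc)
  expect_equal(est_sc$estimate, c_ * est$estimate, tolerance = 1e-10)
  expect_equal(est_sc$se, c_ * est$se, tolerance = 1e-10)
  for (j in c(2, 5)) {
    est_rc <- mr_ivw(recode_variant(d, j))
    expect_equal(est_rc$estimate, est$estimate, tolerance = 1e-10)
    expect_equal(est_rc$se, est$se, tolerance = 1e-10)
  }
})

test_that("p-values agree with the two-sided normal reference", {
  d <- random_dataset(6, seed = 40)
  est <- mr_ivw(d)
  expect_equal(est$p_value, 2 * pnorm(-abs(est$estimate / est$se)),
               tolerance = 1e-12)
  expect_equal(est$ci_upper - est$estimate, qnorm(0.975) * est$se,
               tolerance = 1e-12)
})

test_that("random-effects never reports a smaller SE than fixed-effects", {
  for (seed in c(3, 8, 15)) {
    d <- simulate_univariable(J = 12, theta = 0.2, pleiotropy = "balanced",
                              sd_alpha = 0.02, seed = seed)$dataset
    expect_gte(mr_ivw(d, model = "random")$se, mr_ivw(d, model = "fixed")$se)
  }
})

test_that("multivariable IVW matches the weighted least-squares oracle", {
  for (seed in 1:4) {
    sim <- simulate_multivariable(J = 10, theta = c(0.4, -0.2), seed = seed)
    d <- sim$dataset
    est <- mr_mvivw(d, model = "fixed")
    W <- diag(1 / d$byse^2)
    oracle <- drop(solve(t(d$BX) %*% W %*% d$BX) %*% t(d$BX) %*% W %*% d$by)
    expect_equal(est$estimate, unname(oracle), tolerance = 1e-10)
  }
})

test_that("K = 1 multivariable IVW equals univariable IVW", {
  sim <- simulate_multivariable(J = 9, theta = 0.4, K = 1, seed = 5)
  a <- mr_mvivw(sim$dataset)
  b <- mr_ivw(as_univariable(sim$dataset))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("collinear exposure columns are a non-identification error", {
  sim <- simulate_multivariable(J = 12, theta = 0.4, K = 1, seed = 7)
  d <- sim$dataset
  dd <- mr_mvdataset(cbind(d$BX[, 1], d$BX[, 1]), cbind(d$BXse[, 1], d$BXse[, 1]),
                     d$by, d$byse)
  expect_error(mr_mvivw(dd), "collinear")
})

test_that("multivariable IVW attaches conditional F statistics when nx is given", {
  sim <- simulate_multivariable(J = 20, theta = c(0.3, -0.1), seed = 8)
  with_nx <- mr_mvivw(sim$dataset, nx = 50000)
  without <- mr_mvivw(sim$dataset)
  expect_null(without$strength)
  expect_length(with_nx$strength$conditional_f, 2L)
  expect_true(all(with_nx$strength$conditional_f > 0))
})
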