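test_that("the packaged calcium/fasting-glucose file loads with printed values", {
  fx <- casr_fixtures()
  d <- fx$dataset
  expect_s3_class(d, "mr_dataset")
  expect_length(d$snps, 6L)
  expect_equal(d$bx[1], 0.00625)
  expect_equal(d$bxse[1], 0.00233)
  expect_equal(d$by[1], 0.02805)
  expect_equal(d$byse[1], 0.0122)
  expect_equal(d$bx[6], 0.00651)
  expect_equal(d$by[6], 0.00204)
  expect_true(all(d$bxse > 0) && all(d$byse > 0))
  expect_equal(dim(d$correlation), c(6L, 6L))
})

test_that("loading without a correlation file leaves the slot absent", {
  assoc <- system.file("extdata", "casr_calcium_glucose.csv", package = "mrsummary")
  d <- read_univariable(assoc)
  expect_null(d$correlation)
})

test_that("datasets reject invalid inputs", {
  expect_error(mr_dataset(bx = 1:3, bxse = c(1, 1), by = 1:3, byse = rep(1, 3)),
               "unequal lengths")
  expect_error(mr_dataset(bx = 1:2, bxse = c(1, 0), by = 1:2, byse = c(1, 1)),
               "strictly positive")
  expect_error(mr_dataset(bx = 1:2, bxse = c(1, 1), by = c(NA, 1), byse = c(1, 1)),
               "missing values")
  expect_error(mr_dataset(bx = 1:2, bxse = c(1, 1), by = 1:2, byse = c(1, 1),
                          snps = c("a", "a")),
               "duplicate")
})

test_that("correlation validation enforces the invariants", {
  fx <- casr_fixtures()
  expect_silent(validate_correlation(fx$rho))
  expect_true(any(fx$rho[upper.tri(fx$rho)] < 0))
  expect_silent(validate_correlation(diag(4)))
  # elementwise square of a signed matrix: valid but suspicious (r^2-style)
  expect_warning(validate_correlation(fx$rho^2), "squared-correlation")
  # r^2-style matrix with diagonal != 1 is a hard error
  bad <- 0.9 * fx$rho^2
  expect_error(validate_correlation(bad), "diagonal")
  asym <- fx$rho; asym[1, 2] <- asym[1, 2] + 1e-6
  expect_error(validate_correlation(asym), "symmetric")
  big <- diag(2); big[1, 2] <- big[2, 1] <- 1.5
  expect_error(validate_correlation(big))
})

test_that("correlation matrices are aligned to association rows by variant ID", {
  fx <- casr_fixtures()
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  rho_perm <- fx$rho[perm, perm]
  d <- mr_dataset(fx$dataset$bx, fx$dataset$bxse, fx$dataset$by,
                  fx$dataset$byse, snps = fx$dataset$snps,
                  correlation = rho_perm)
  expect_equal(d$correlation, fx$dataset$correlation)
  # IDs missing from the correlation matrix are an error
  expect_error(
    mr_dataset(fx$dataset$bx, fx$dataset$bxse, fx$dataset$by, fx$dataset$byse,
               snps = fx$dataset$snps,
               correlation = fx$rho[1:5, 1:5]),
    "lacks variants")
})

test_that("write/read round-trips a dataset exactly", {
  fx <- casr_fixtures()
  assoc <- system.file("extdata", "casr_calcium_glucose.csv", package = "mrsummary")
  d <- read_univariable(assoc)
  tmp <- tempfile(fileext = ".csv")
  write_univariable(d, tmp)
  d2 <- read_univariable(tmp)
  expect_identical(d2$bx, d$bx)
  expect_identical(d2$bxse, d$bxse)
  expect_identical(d2$by, d$by)
  expect_identical(d2$byse, d$byse)
  expect_identical(d2$snps, d$snps)
  tmp2 <- tempfile(fileext = ".csv")
  write_correlation(fx$rho, tmp2)
  expect_identical(read_correlation(tmp2), fx$rho)
})

test_that("multivariable files load with exposures in column order", {
  sim <- simulate_multivariable(J = 28, theta = c(0.5, 0, 0.2), K = 3,
                                seed = 42)
  d <- sim$dataset
  tab <- data.frame(snp = d$snps, bx_ldl = d$BX[, 1], bxse_ldl = d$BXse[, 1],
                    bx_hdl = d$BX[, 2], bxse_hdl = d$BXse[, 2],
                    bx_tg = d$BX[, 3], bxse_tg = d$BXse[, 3],
                    by = d$by, byse = d$byse)
  tmp <- tempfile(fileext = ".csv")
  write.csv(tab, tmp, row.names = FALSE, quote = FALSE)
  md <- read_multivariable(tmp)
  expect_equal(dim(md$BX), c(28L, 3L))
  expect_identical(md$exposures, c("ldl", "hdl", "tg"))
  expect_equal(unname(md$BX[, 1]), tab$bx_ldl)
  # absent exposure correlation file defaults to the identity
  expect_equal(unname(md$exposure_correlation), diag(3))
  # ragged exposure columns are rejected
  tab_bad <- tab[, setdiff(names(tab), "bxse_tg")]
  tmp_bad <- tempfile(fileext = ".csv")
  write.csv(tab_bad, tmp_bad, row.names = FALSE, quote = FALSE)
  expect_error(read_multivariable(tmp_bad), "ragged")
})

test_that("a single-exposure multivariable dataset embeds losslessly", {
  sim <- simulate_multivariable(J = 10, theta = 0.4, K = 1, seed = 3)
  u <- as_univariable(sim$dataset)
  expect_s3_class(u, "mr_dataset")
  expect_equal(u$bx, unname(sim$dataset$BX[, 1]))
  expect_equal(u$bxse, unname(sim$dataset$BXse[, 1]))
  expect_equal(u$by, sim$dataset$by)
})
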