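# Seeded generator of two-sample summary statistics with known truth. The
# generating model is the one every estimator in the package assumes:
#   bx_j ~ Normal(gamma_j, sx_j^2),  by_j ~ Normal(theta' gamma_j + alpha_j, sy_j^2)
# with standard errors scaling as 1/sqrt(n) (traits on a standardized scale),
# optional linkage disequilibrium correlating both the true effects and the
# estimation errors across variants through rho, and optional horizontal
# pleiotropy alpha_j (balanced: zero-mean; directional: shifted mean).
# Instrument strength is parameterized by the target mean F statistic:
# E[(bx/sx)^2] = 1 + gamma^2/sx^2, so sd(gamma) = sx * sqrt(mean_f - 1).

strength_to_meanf <- function(strength) {
  if (is.numeric(strength)) return(strength)
  switch(match.arg(strength, c("strong", "moderate", "weak")),
         strong = 100, moderate = 30, weak = 4)
}

pleiotropy_alpha <- function(J, regime, sd_alpha, mean_alpha) {
  switch(match.arg(regime, c("none", "balanced", "directional")),
         none = numeric(J),
         balanced = stats::rnorm(J, 0, sd_alpha),
         directional = stats::rnorm(J, mean_alpha, sd_alpha))
}

mvn_draw <- function(mu, sd_vec, rho) {
  if (is.null(rho)) return(stats::rnorm(length(mu), mu, sd_vec))
  Sigma <- rho * (sd_vec %o% sd_vec)
  drop(MASS::mvrnorm(1, mu, Sigma))
}

#' Simulate univariable two-sample summary statistics with known truth
#'
#' @param J number of variants.
#' @param theta true causal effect (default 0).
#' @param strength `"strong"`, `"moderate"`, `"weak"`, or a numeric target
#'   mean F statistic (default `"moderate"` = 30; weak = 4, strong = 100).
#' @param pleiotropy `"none"` (default), `"balanced"`, or `"directional"`.
#' @param sd_alpha,mean_alpha pleiotropy scale (default 0.01) and
#'   directional-shift mean (default 0.01).
#' @param rho optional variant correlation matrix (linkage disequilibrium);
#'   correlates both the true effects and the estimation errors.
#' @param nx,ny exposure and outcome sample sizes (defaults 50000, 50000).
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @return a list with `dataset` (an [mr_dataset], carrying `rho` when
#'   given) and `truth` (class `mr_simtruth`: theta, gamma, alpha, rho, nx,
#'   ny, regime labels, seed).
#' @examples
#' sim <- simulate_univariable(J = 10, theta = 0.5, seed = 1)
#' mr_ivw(sim$dataset)
#' @export
simulate_univariable <- function(J, theta = 0, strength = "moderate",
                                 pleiotropy = "none", sd_alpha = 0.01,
                                 mean_alpha = 0.01, rho = NULL,
                                 nx = 50000, ny = 50000, seed = 1) {
  stopifnot(J >= 1)
  if (!is.null(rho)) rho <- validate_correlation(rho, warn_unsigned = FALSE)
  mean_f <- strength_to_meanf(strength)
  sx <- rep(1 / sqrt(nx), J)
  sy <- rep(1 / sqrt(ny), J)
  sd_gamma <- sx[1] * sqrt(max(mean_f - 1, 0))
  with_seed(seed, {
    gamma <- if (is.null(rho)) stats::rnorm(J, 0, sd_gamma) else
      mvn_draw(numeric(J), rep(sd_gamma, J), rho)
    alpha <- pleiotropy_alpha(J, pleiotropy, sd_alpha, mean_alpha)
    bx <- mvn_draw(gamma, sx, rho)
    by <- mvn_draw(theta * gamma + alpha, sy, rho)
    truth <- structure(list(theta = theta, gamma = gamma, alpha = alpha,
                            rho = rho, nx = nx, ny = ny,
                            strength = strength, pleiotropy = pleiotropy,
                            seed = seed),
                       class = "mr_simtruth")
    list(dataset = mr_dataset(bx, sx, by, sy, correlation = rho),
         truth = truth)
  })
}

#' Simulate multivariable two-sample summary statistics with known truth
#'
#' @param J number of variants; `K` number of exposures.
#' @param theta true causal effect vector (length K; default zeros).
#' @param K number of exposures (default `length(theta)`).
#' @param strength as in [simulate_univariable].
#' @param pleiotropy,sd_alpha,mean_alpha as in [simulate_univariable].
#' @param exposure_correlation optional K x K correlation of exposure
#'   association errors (overlapping samples); identity when NULL.
#' @param collinearity in \[0, 1): fraction of each later exposure's true
#'   effects copied from exposure 1, to engineer weak conditional
#'   identification (default 0).
#' @param rho optional variant correlation matrix.
#' @param nx,ny sample sizes (nx length 1 or K).
#' @param seed RNG seed.
#' @return list with `dataset` ([mr_mvdataset]) and `truth` (`mr_simtruth`
#'   with a J x K `gamma` matrix).
#' @export
simulate_multivariable <- function(J, theta = c(0, 0), K = length(theta),
                                   strength = "moderate", pleiotropy = "none",
                                   sd_alpha = 0.01, mean_alpha = 0.01,
                                   exposure_correlation = NULL,
                                   collinearity = 0, rho = NULL,
                                   nx = 50000, ny = 50000, seed = 1) {
  stopifnot(J >= 1, K >= 1, length(theta) == K, collinearity >= 0, collinearity < 1)
  if (!is.null(rho)) rho <- validate_correlation(rho, warn_unsigned = FALSE)
  nx <- if (length(nx) == 1L) rep(nx, K) else nx
  mean_f <- strength_to_meanf(strength)
  SX <- matrix(rep(1 / sqrt(nx), each = J), J, K)
  sy <- rep(1 / sqrt(ny), J)
  rho_x <- exposure_correlation %||% diag(K)
  with_seed(seed, {
    gamma <- matrix(stats::rnorm(J * K), J, K) *
      matrix(rep(1 / sqrt(nx) * sqrt(max(mean_f - 1, 0)), each = J), J, K)
    if (collinearity > 0 && K > 1) {
      for (k in 2:K) {
        gamma[, k] <- collinearity * gamma[, 1] +
          sqrt(1 - collinearity^2) * gamma[, k]
      }
    }
    alpha <- pleiotropy_alpha(J, pleiotropy, sd_alpha, mean_alpha)
    ch_x <- chol(rho_x)
    EX <- matrix(stats::rnorm(J * K), J, K) %*% ch_x  # exposure-error correlation
    ey <- stats::rnorm(J)
    if (!is.null(rho)) {
      # LD correlates errors across variants within each association column.
      Lr <- chol_lower(rho)
      EX <- Lr %*% EX
      ey <- drop(Lr %*% ey)
    }
    BX <- gamma + EX * SX
    by <- drop(gamma %*% theta) + alpha + ey * sy
    truth <- structure(list(theta = theta, gamma = gamma, alpha = alpha,
                            rho = rho, nx = nx, ny = ny,
                            strength = strength, pleiotropy = pleiotropy,
                            seed = seed),
                       class = "mr_simtruth")
    list(dataset = mr_mvdataset(BX, SX, by, sy, correlation = rho,
                                exposure_correlation = if (is.null(exposure_correlation)) NULL else rho_x),
         truth = truth)
  })
}

#' In-package worked-example fixtures: the CASR gene region
#'
#' Returns the six-variant dataset of associations with serum calcium
#' (exposure) and fasting glucose (outcome) from the *CASR* gene region, its
#' 6 x 6 signed variant correlation matrix before allele harmonization
#' (`rho`), the harmonized matrix (`rho_signed`), the flip vector relating
#' the two, and the sample sizes (`nx = 6351`, `ny = 133010`). The dataset's
#' own correlation slot holds `rho` as distributed. These are the package's
#' built-in worked-example data for correlated-variant and
#' principal-component analyses.
#'
#' @return a list with elements `dataset` ([mr_dataset]), `rho`,
#'   `rho_signed`, `flip`, `nx`, `ny`.
#' @examples
#' fx <- casr_fixtures()
#' all.equal(flip_correlation(fx$rho, fx$flip), fx$rho_signed)
#' @export
casr_fixtures <- function() {
  assoc <- system.file("extdata", "casr_calcium_glucose.csv",
                       package = "mrsummary", mustWork = TRUE)
  rho_path <- system.file("extdata", "casr_rho.csv",
                          package = "mrsummary", mustWork = TRUE)
  signed_path <- system.file("extdata", "casr_rho_signed.csv",
                             package = "mrsummary", mustWork = TRUE)
  dataset <- read_univariable(assoc, corr_path = rho_path)
  list(dataset = dataset,
       rho = dataset$correlation,
       rho_signed = read_correlation(signed_path),
       flip = c(+1, +1, -1, +1, -1, +1),
       nx = 6351, ny = 133010)
}
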