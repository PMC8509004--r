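#' Analytic power of the slope t-test
#'
#' Power of the two-sided test of slope = 0 in simple linear regression of
#' expression on age, from the noncentral t distribution: with design sum of
#' squares Sxx and residual standard deviation sigma, the noncentrality is
#' ncp = slope * sqrt(Sxx) / sigma and power is the probability that |T'|
#' with n - 2 df exceeds the two-sided critical value. At slope 0 this is
#' exactly the test size alpha.
#'
#' @param slope True slope (expression units per year).
#' @param sigma Residual standard deviation (> 0).
#' @param ages Numeric vector of design ages; alternatively give \code{n}
#'   for the expected design of \code{n} ages uniform on \\[0.33, 40\\]
#'   (Sxx = n * range^2 / 12).
#' @param n Number of observations when \code{ages} is not supplied.
#' @param alpha Type-I error (default 0.05).
#' @return Power in \\[0, 1\\].
#' @export
#' @examples
#' power_slope_test(slope = 0, sigma = 5, n = 42)   # = alpha
#' power_slope_test(slope = 1, sigma = 5, n = 42)   # near 1
power_slope_test <- function(slope, sigma, ages = NULL, n = NULL,
                             alpha = 0.05) {
  stopifnot(sigma > 0, alpha > 0, alpha < 1)
  if (is.null(ages)) {
    stopifnot(!is.null(n), n >= 3)
    sxx <- n * (40 - 1 / 3)^2 / 12
  } else {
    n <- length(ages)
    if (n < 3) stop("need at least 3 design ages")
    sxx <- sum((ages - mean(ages))^2)
    if (sxx == 0) stop("zero age variance in the design")
  }
  df <- n - 2
  ncp <- slope * sqrt(sxx) / sigma
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp = ncp) + 1 - stats::pt(tcrit, df, ncp = ncp)
}

#' Monte-Carlo power of the slope t-test
#'
#' Companion simulation estimate to [power_slope_test()]: draws replicate
#' datasets from the linear model, fits [fit_age_regression()] on each, and
#' returns the rejection fraction.
#'
#' @inheritParams power_slope_test
#' @param reps Number of replicates (default 2000).
#' @param seed Integer seed.
#' @return List: \code{power} (rejection fraction), \code{se} (binomial
#'   standard error), \code{reps}.
#' @export
mc_power_slope_test <- function(slope, sigma, ages = NULL, n = NULL,
                                alpha = 0.05, reps = 2000, seed = 1L) {
  set.seed(seed)
  if (is.null(ages)) {
    stopifnot(!is.null(n), n >= 3)
    ages <- stats::runif(n, 1 / 3, 40)
  }
  n <- length(ages)
  rej <- vapply(seq_len(reps), function(i) {
    y <- slope * ages + stats::rnorm(n, 0, sigma)
    fit_age_regression(ages, y)$p < alpha
  }, TRUE)
  p <- mean(rej)
  list(power = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Empirical type-I error of the screen on simulated null genes
#'
#' Simulates \code{n_pairs} gene-region pairs with zero true age effect via
#' [simulate_brainspan()] (one region, \code{n_samples} donors, full
#' coverage), fits the slope test on each, and returns the fraction of raw
#' p-values below \code{alpha}. Under a calibrated test this fraction
#' matches alpha to binomial error.
#'
#' @param n_pairs Number of null gene-region pairs (default 10000).
#' @param n_samples Samples per pair (default 42).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Integer seed.
#' @param noise_sd Residual standard deviation of the simulated expression
#'   (default 10).
#' @return List: \code{rejection_rate}, \code{n_pairs}, \code{p_values}.
#' @export
empirical_type1 <- function(n_pairs = 10000, n_samples = 42, alpha = 0.05,
                            seed = 1L, noise_sd = 10) {
  stopifnot(alpha >= 0, alpha <= 1, n_pairs >= 1, n_samples >= 3)
  sim <- simulate_brainspan(n_genes = n_pairs, n_donors = n_samples,
                            regions = "PVC", frac_age_linear = 0,
                            noise_sd = noise_sd, missing_rate = 0,
                            intercept_range = c(50, 100), seed = seed)
  fits <- .fit_region(sim$samples$age_years, sim$expr)
  list(rejection_rate = mean(fits$p < alpha), n_pairs = n_pairs,
       p_values = fits$p)
}
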