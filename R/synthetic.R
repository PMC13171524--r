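#' @importFrom stats rnorm rt runif var
NULL

# set.seed only when the caller supplies one; generators are then pure
# functions of the seed.
ca_maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Sample a synthetic cross set with a controlled variance ratio
#'
#' Draws `k` cross means from Normal(`mu_mean`, `mu_var`) and segregation
#' standard deviations from Normal(`1 + 2*sqrt(c*mu_var)`, `c*mu_var`),
#' so that roughly 95% of the sigma* fall into
#' `[1, 1 + 4*sqrt(c*mu_var)]`. Values below `sd_floor` are rejected and
#' redrawn individually. The whole set is resampled until the sample
#' variance of the sigma* deviates from the target `c * mu_var` by less
#' than `tolerance`, emulating cross sets whose variability of segregation
#' standard deviations is a chosen multiple `c` of the variability of the
#' cross means.
#'
#' `mu_mean` and `mu_var` default to the grand mean and variance of the
#' bundled barley cross means, for which the observed ratio is about 0.05.
#'
#' @param k Number of crosses.
#' @param c Scaling factor: target `Var(sigma*) = c * mu_var` (positive).
#' @param mu_mean,mu_var Sampling moments for the cross means; `NULL` means
#'   take them from [barley_crosses()].
#' @param sd_floor Lower boundary for sigma* (default 1, the smallest value
#'   observed in the experimental set).
#' @param tolerance Maximum absolute deviation of the achieved
#'   `Var(sigma*)` from the target (default 0.01).
#' @param max_rounds Resampling cap before giving up with an error.
#' @param seed Optional integer seed; identical seeds give identical sets.
#' @return A [cross_set()] with `seg_var = sigma*^2`.
#' @examples
#' sample_cross_set(k = 20, c = 0.05, seed = 1)
#' @export
sample_cross_set <- function(k = 20, c = 0.05, mu_mean = NULL, mu_var = NULL,
                             sd_floor = 1, tolerance = 0.01,
                             max_rounds = 1e5, seed = NULL) {
  if (c <= 0) ca_stop_validation("'c' must be positive")
  if (tolerance <= 0) ca_stop_validation("'tolerance' must be positive")
  if (is.null(mu_mean) || is.null(mu_var)) {
    b <- barley_crosses()
    if (is.null(mu_mean)) mu_mean <- mean(b$mu)
    if (is.null(mu_var)) mu_var <- var(b$mu)
  }
  ca_maybe_seed(seed)
  target <- c * mu_var
  sd_mean <- sd_floor + 2 * sqrt(target)
  sd_sd <- sqrt(target)
  for (round in seq_len(max_rounds)) {
    sig <- rnorm(k, sd_mean, sd_sd)
    # floor by individual rejection, not truncation (no atom at the floor)
    bad <- which(sig < sd_floor)
    guard <- 0
    while (length(bad) > 0) {
      sig[bad] <- rnorm(length(bad), sd_mean, sd_sd)
      bad <- which(sig < sd_floor)
      guard <- guard + 1
      if (guard > 1e4)
        ca_stop_numerical("sigma* floor rejection did not terminate; ",
                          "check 'c' and 'sd_floor'")
    }
    if (abs(var(sig) - target) < tolerance) {
      mu <- rnorm(k, mu_mean, sqrt(mu_var))
      return(cross_set(mu = mu, seg_var = sig^2,
                       id = paste0("sim_", seq_len(k))))
    }
  }
  ca_stop_numerical("no sigma* sample hit |Var(sigma*) - ", format(target),
                    "| < ", tolerance, " within ", max_rounds,
                    " rounds; consider a larger tolerance")
}

#' Perturb segregation variances with prediction error
#'
#' Adds random prediction error to each cross's segregation variance. The
#' error scale is set through the mean absolute variance error (MAVE): per
#' cross, `MAVE_i = mave_fraction * seg_var_i`, and the error is drawn from
#' Normal(0, sd = `MAVE_i * sqrt(pi/2)`), so that the expected absolute
#' error equals `MAVE_i` (MAD of a centered normal = sd * sqrt(2/pi)). A
#' perturbed variance that would be non-positive is redrawn for that cross,
#' since downstream computations require positive variances. Cross means
#' are untouched.
#'
#' @param cross_set A [cross_set()].
#' @param mave_fraction MAVE as a fraction of the true segregation variance
#'   (e.g. 0.05, 0.10, 0.25). A value of 0 returns the input unchanged
#'   without consuming random numbers.
#' @param seed Optional integer seed.
#' @return A new [cross_set()] with noisy `seg_var`.
#' @export
add_variance_noise <- function(cross_set, mave_fraction, seed = NULL) {
  cs <- as_cross_set(cross_set)
  if (!is.numeric(mave_fraction) || length(mave_fraction) != 1 ||
      mave_fraction < 0)
    ca_stop_validation("'mave_fraction' must be a single non-negative number")
  if (mave_fraction == 0) return(cs)
  ca_maybe_seed(seed)
  mave <- mave_fraction * cs$seg_var
  err <- rnorm(nrow(cs), 0, mave * sqrt(pi / 2))
  noisy <- cs$seg_var + err
  bad <- which(noisy <= 0)
  guard <- 0
  while (length(bad) > 0) {
    noisy[bad] <- cs$seg_var[bad] + rnorm(length(bad), 0,
                                          mave[bad] * sqrt(pi / 2))
    bad <- which(noisy <= 0)
    guard <- guard + 1
    if (guard > 1e4)
      ca_stop_numerical("positivity rejection for noisy variances did not ",
                        "terminate")
  }
  out <- cs
  out$seg_var <- noisy
  out
}

# moments of the noncentral t used to center/scale the skewed family
ca_nct_mean <- function(nu, ncp) ncp * sqrt(nu / 2) * exp(lgamma((nu - 1) / 2) - lgamma(nu / 2))
ca_nct_var <- function(nu, ncp) nu * (1 + ncp^2) / (nu - 2) - ca_nct_mean(nu, ncp)^2

#' Sample a non-normal trait population
#'
#' Draws `n` trait values from one of four families, rescaled to a target
#' variance and centered on a common mean:
#' \describe{
#'   \item{`"skew_t"`}{right-skewed noncentral t, 10 degrees of freedom,
#'     noncentrality 3.}
#'   \item{`"heavy_t"`}{heavy-tailed central t, 10 degrees of freedom
#'     (excess kurtosis 1).}
#'   \item{`"bimodal"`}{equal mix of two normals whose means are 3 trait
#'     units apart (`floor(n/2)` from the lower, `ceiling(n/2)` from the
#'     upper component); component SDs follow from the target variance.}
#'   \item{`"normal"`}{plain normal control (under which the
#'     order-statistics prediction is exact).}
#' }
#'
#' @param n Sample size.
#' @param family One of `"skew_t"`, `"heavy_t"`, `"bimodal"`, `"normal"`.
#' @param center Common mean on which samples are centered (trait units).
#' @param target_var Variance to scale to; `NULL` draws it uniformly from
#'   `[1, 20]` (from `[2.5, 20]` for the bimodal family, whose mean shift
#'   of 3 already contributes variance 2.25).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` trait values.
#' @export
sample_non_normal_population <- function(n,
                                         family = c("skew_t", "heavy_t",
                                                    "bimodal", "normal"),
                                         center = 92, target_var = NULL,
                                         seed = NULL) {
  family <- match.arg(family)
  if (n < 2) ca_stop_validation("'n' must be at least 2")
  ca_maybe_seed(seed)
  if (is.null(target_var))
    target_var <- if (family == "bimodal") runif(1, 2.5, 20) else
      runif(1, 1, 20)
  if (target_var <= 0) ca_stop_validation("'target_var' must be positive")
  switch(family,
    skew_t = {
      m <- ca_nct_mean(10, 3); v <- ca_nct_var(10, 3)
      a <- sqrt(target_var / v)
      center + a * (rt(n, df = 10, ncp = 3) - m)
    },
    heavy_t = {
      a <- sqrt(target_var / (10 / 8))
      center + a * rt(n, df = 10)
    },
    bimodal = {
      if (target_var <= 2.25)
        ca_stop_validation("bimodal target variance must exceed 2.25 ",
                           "(the contribution of the mean shift of 3)")
      sdc <- sqrt(target_var - 2.25)
      n1 <- floor(n / 2); n2 <- ceiling(n / 2)
      c(rnorm(n1, center - 1.5, sdc), rnorm(n2, center + 1.5, sdc))
    },
    normal = rnorm(n, center, sqrt(target_var))
  )
}
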