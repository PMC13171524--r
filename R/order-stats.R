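#' @importFrom stats dnorm pnorm qnorm integrate
NULL

# ---- internal: standardized moments by adaptive quadrature ------------------

# Integration window for the standardized integrand. Beyond |z| = 10 the
# density of any order statistic with n <= 1e4 carries mass < 1e-20.
.ca_zlim <- 10
.ca_tol <- 1e-10

# log of the order-statistic coefficient Gamma(n+1)/(Gamma(r) Gamma(n-r+1)),
# evaluated in log space so that n > 170 does not overflow.
ca_lcoef <- function(n, r) lgamma(n + 1) - lgamma(r) - lgamma(n - r + 1)

# standardized density of the r-th order statistic of n iid N(0,1) draws,
# with the gamma extension to continuous n (and r); log CDF / log survival
# keep the tails stable for large n.
ca_std_density <- function(z, n, r) {
  lF <- pnorm(z, log.p = TRUE)
  lS <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  exp(ca_lcoef(n, r) + (r - 1) * lF + (n - r) * lS + dnorm(z, log = TRUE))
}

# E[Z_(r:n)^moment] for standard normal order statistics, by adaptive
# quadrature on [-10, 10]; memoized (moment 1 and 2) because the greedy
# allocator re-evaluates many (n, r) pairs.
ca_std_moment <- function(n, r, moment = 1L) {
  store <- if (moment == 1L) .ca_cache$e1 else .ca_cache$e2
  key <- paste(format(n, digits = 15), format(r, digits = 15), sep = "|")
  hit <- store[[key]]
  if (!is.null(hit)) return(hit)
  f <- function(z) z^moment * ca_std_density(z, n, r)
  # r <= n: mass outside +-10 is < 1e-20 for n <= 1e4. The gamma-extended
  # edge r in (n, ceiling(n)] has a fractional negative exponent on the
  # survival function that fattens the upper tail; integrate over the whole
  # line there.
  lim <- if (r > n) Inf else .ca_zlim
  val <- tryCatch(
    integrate(f, -lim, lim, rel.tol = .ca_tol, abs.tol = .ca_tol,
              subdivisions = 400L)$value,
    error = function(e) ca_stop_numerical(
      "quadrature failed for order statistic (n = ", n, ", r = ", r,
      ", moment = ", moment, "): ", conditionMessage(e)))
  store[[key]] <- val
  val
}

ca_check_spec <- function(n, r, sd) {
  if (!is.numeric(sd) || any(sd <= 0))
    ca_stop_validation("'sd' must be positive")
  if (!is.numeric(n) || any(n < 1))
    ca_stop_validation("'n' must be >= 1")
  if (!is.numeric(r) || any(r < 1))
    ca_stop_validation("rank 'r' must be >= 1")
  if (any(r > ceiling(n)))
    ca_stop_validation("rank 'r' must not exceed the sample size 'n'")
  invisible(NULL)
}

# ---- exported: order-statistic moments --------------------------------------

#' Density of a normal order statistic
#'
#' Density of the r-th smallest value among `n` independent draws from a
#' normal distribution. The combinatorial coefficient is evaluated through
#' gamma functions, so `n` may be any real value >= `r` (continuous
#' extension); the density remains proper.
#'
#' @param x Numeric vector of evaluation points (trait units).
#' @param n Sample size (real, >= 1).
#' @param r Rank, `1 <= r <= ceiling(n)`; `r = n` is the maximum.
#' @param mean,sd Location and scale of the parent normal distribution.
#' @return Numeric vector of density values.
#' @examples
#' dorderstat(0, n = 2, r = 2)       # 2 * pnorm(0) * dnorm(0)
#' integrate(dorderstat, -8, 8, n = 7.5, r = 3)  # integrates to 1
#' @export
dorderstat <- function(x, n, r, mean = 0, sd = 1) {
  ca_check_spec(n, r, sd)
  ca_std_density((x - mean) / sd, n, r) / sd
}

#' Expectation of a normal order statistic
#'
#' Computes E[X_(r:n)] for a normal parent by adaptive quadrature of the
#' order-statistic density. Location-scale equivariant: the standardized
#' expectation is computed once (and memoized) and rescaled.
#'
#' @inheritParams dorderstat
#' @return Expected value in trait units.
#' @examples
#' eorderstat(2, 2)            # 1 / sqrt(pi)
#' eorderstat(5, 5)            # 1.16296...
#' @export
eorderstat <- function(n, r, mean = 0, sd = 1) {
  ca_check_spec(n, r, sd)
  mean + sd * ca_std_moment(n, r, 1L)
}

#' Variance of a normal order statistic
#'
#' Var[X_(r:n)] = E[X^2] - E[X]^2 with both moments from quadrature; scales
#' with `sd^2`.
#'
#' @inheritParams dorderstat
#' @return Variance in squared trait units.
#' @examples
#' vorderstat(1, 1)   # variance of the parent, 1
#' vorderstat(2, 2)   # 1 - 1/pi
#' @export
vorderstat <- function(n, r, mean = 0, sd = 1) {
  ca_check_spec(n, r, sd)
  sd^2 * (ca_std_moment(n, r, 2L) - ca_std_moment(n, r, 1L)^2)
}

# ---- internal: the standardized selection function d(n, s) ------------------

# d(n, s) = (1/s) sum_{j=0}^{s-1} E[Z_(n-j : n)], the standardized expected
# mean of the s greatest of n. E(Y_i) = mu_i + sigma_i * d(n_i, s_i).
# Integer n values are cached in per-s lookup vectors because the greedy
# loop and the experiment replicates revisit the same (n, s) pairs heavily.
ca_std_top_mean <- function(n, s) {
  if (n == round(n)) {
    key <- as.character(s)
    v <- .ca_cache$dtab[[key]]
    if (!is.null(v) && n <= length(v) && !is.na(v[n])) return(v[n])
    val <- mean(vapply(0:(s - 1), function(j) ca_std_moment(n, n - j), 0))
    if (is.null(v)) v <- rep(NA_real_, n)
    if (length(v) < n) v <- c(v, rep(NA_real_, n - length(v)))
    v[n] <- val
    .ca_cache$dtab[[key]] <- v
    val
  } else {
    mean(vapply(0:(s - 1), function(j) ca_std_moment(n, n - j), 0))
  }
}

# ensure the d-table for a given s covers n = s..nmax (batch pre-fill)
ca_std_top_mean_fill <- function(s, nmax) {
  for (n in s:nmax) ca_std_top_mean(n, s)
  invisible(NULL)
}

# d/dn of the continuous extension of d(n, s): fourth-order central
# difference of the gamma-extended expression. This mirrors an automatic
# differentiation of the continuous target; integer evaluation points are
# cached per s.
ca_std_top_grad <- function(n, s, h = 1e-3) {
  grad1 <- function(n) {
    (ca_std_top_mean(n - 2 * h, s) - 8 * ca_std_top_mean(n - h, s) +
       8 * ca_std_top_mean(n + h, s) - ca_std_top_mean(n + 2 * h, s)) /
      (12 * h)
  }
  if (n == round(n)) {
    key <- as.character(s)
    v <- .ca_cache$gtab[[key]]
    if (!is.null(v) && n <= length(v) && !is.na(v[n])) return(v[n])
    val <- grad1(n)
    if (is.null(v)) v <- rep(NA_real_, n)
    if (length(v) < n) v <- c(v, rep(NA_real_, n - length(v)))
    v[n] <- val
    .ca_cache$gtab[[key]] <- v
    val
  } else {
    grad1(n)
  }
}

# ---- exported: selected-fraction expectations -------------------------------

#' Expected mean of the top-s selected fraction of a normal sample
#'
#' Expectation of the unweighted mean of the `s` greatest order statistics
#' of `n` independent normal draws: the expected mean of the selected
#' fraction under within-family truncation selection with finite family
#' size.
#'
#' @param mean,sd Location and scale of the (phenotypic) normal distribution.
#' @param n Family size (positive integer).
#' @param s Number selected, `1 <= s <= n`.
#' @return Expected mean of the selected fraction, in trait units; equals
#'   `mean` when `s == n` and exceeds it otherwise.
#' @examples
#' top_fraction_expectation(0, 1, n = 2, s = 1)  # 1/sqrt(pi)
#' top_fraction_expectation(90, 2, n = 20, s = 5)
#' @export
top_fraction_expectation <- function(mean, sd, n, s) {
  if (!is.numeric(sd) || sd <= 0) ca_stop_validation("'sd' must be positive")
  if (n != round(n) || s != round(s) || n < 1 || s < 1)
    ca_stop_validation("'n' and 's' must be positive integers")
  if (s > n)
    ca_stop_validation("cannot select s = ", s, " from a family of n = ", n)
  mean + sd * ca_std_top_mean(as.integer(n), as.integer(s))
}

#' Expected top-fraction mean for an arbitrary continuous distribution
#'
#' Plug-in version of [top_fraction_expectation()]: the normal density and
#' CDF in the order-statistic integrand are replaced by a user-supplied
#' pair. Useful when a more realistic trait distribution is known.
#'
#' @param pdf,cdf Vectorized density and distribution functions of the
#'   parent distribution. Their consistency (pdf integrates to 1; its
#'   partial integrals match `cdf`) is verified up to `check_tol` unless
#'   `check = FALSE`.
#' @param n,s Family size and number selected (positive integers, `s <= n`).
#' @param lower,upper Support of the distribution for the quadrature.
#' @param check Verify pdf/cdf consistency first.
#' @param check_tol Tolerance for the consistency check.
#' @return Expected mean of the `s` greatest of `n` draws.
#' @examples
#' # uniform(0, 1): E[max of 3] = 3/4
#' generic_top_fraction_expectation(dunif, punif, n = 3, s = 1,
#'                                  lower = 0, upper = 1)
#' @export
generic_top_fraction_expectation <- function(pdf, cdf, n, s,
                                             lower = -Inf, upper = Inf,
                                             check = TRUE, check_tol = 1e-6) {
  if (n != round(n) || s != round(s) || n < 1 || s < 1)
    ca_stop_validation("'n' and 's' must be positive integers")
  if (s > n)
    ca_stop_validation("cannot select s = ", s, " from a family of n = ", n)
  if (check) {
    total <- integrate(pdf, lower, upper, rel.tol = 1e-9)$value
    if (abs(total - 1) > check_tol)
      ca_stop_validation("pdf does not integrate to 1 (got ",
                         format(total), ")")
    # spot-check cdf against partial integrals of pdf
    lo <- if (is.finite(lower)) lower else -20
    hi <- if (is.finite(upper)) upper else 20
    for (q in lo + c(0.25, 0.45, 0.5, 0.55, 0.75) * (hi - lo)) {
      part <- integrate(pdf, lower, q, rel.tol = 1e-9)$value
      if (abs(part - cdf(q)) > check_tol)
        ca_stop_validation("cdf inconsistent with pdf at x = ", format(q))
    }
  }
  e_rank <- function(r) {
    lc <- ca_lcoef(n, r)
    f <- function(x) {
      Fx <- pmin(pmax(cdf(x), 0), 1)
      # guard the support edges: a zero exponent must kill the -Inf log,
      # not produce 0 * -Inf = NaN
      lw <- rep(lc, length(x))
      if (r > 1) lw <- lw + (r - 1) * log(Fx)
      if (n > r) lw <- lw + (n - r) * log1p(-Fx)
      x * exp(lw) * pdf(x)
    }
    tryCatch(
      integrate(f, lower, upper, rel.tol = 1e-9, abs.tol = 1e-9,
                subdivisions = 400L)$value,
      error = function(e) ca_stop_numerical(
        "quadrature failed for plug-in order statistic (n = ", n, ", r = ",
        r, "): ", conditionMessage(e)))
  }
  mean(vapply(n - seq_len(s) + 1, e_rank, 0))
}

#' Infinite-population truncation selection differential
#'
#' The classical selection differential S = phi(Phi^-1(1 - alpha)) * sd /
#' alpha for truncation selection of a fraction `alpha`, which ignores
#' finite sample size and therefore overestimates the differential realized
#' in finite families.
#'
#' @param sd Phenotypic standard deviation (trait units).
#' @param alpha Selected fraction, in (0, 1]; `alpha = 1` means no
#'   selection and returns 0.
#' @return Selection differential in trait units.
#' @examples
#' truncation_selection_differential(1, 0.5)  # dnorm(0) / 0.5
#' @export
truncation_selection_differential <- function(sd, alpha) {
  if (!is.numeric(sd) || any(sd <= 0))
    ca_stop_validation("'sd' must be positive")
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha > 1))
    ca_stop_validation("'alpha' must lie in (0, 1]")
  ifelse(alpha == 1, 0, dnorm(qnorm(1 - alpha)) * sd / alpha)
}
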