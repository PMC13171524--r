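#' Discrete marginal gain of one additional individual
#'
#' E(G_i)(n_i + 1) - E(G_i)(n_i): the gain in a cross's expected genetic
#' value from growing its family by one. Equal to
#' `sqrt(H2) * sigma*_i * (d(n_i + 1, s_i) - d(n_i, s_i))` where d is the
#' standardized expected top-fraction mean, so the gain is strictly
#' positive, decreasing in `n_i` (concavity) and linear in the segregation
#' standard deviation.
#'
#' @param cross_set A [cross_set()].
#' @param n Current family sizes (one per cross, `n_i >= s_i`).
#' @param scenario A [scenario()].
#' @return Numeric vector of per-cross gains in E(G_i) units.
#' @export
marginal_gain <- function(cross_set, n, scenario) {
  cs <- as_cross_set(cross_set)
  s <- ca_scenario_s(scenario, nrow(cs))
  if (length(n) != nrow(cs) || any(n < s))
    ca_stop_validation("'n' must supply one family size per cross, n_i >= s_i")
  H <- sqrt(scenario$H2)
  vapply(seq_len(nrow(cs)), function(i) {
    H * sqrt(cs$seg_var[i]) *
      (ca_std_top_mean(n[i] + 1L, s[i]) - ca_std_top_mean(n[i], s[i]))
  }, 0)
}

#' Continuous gradient of E(G_i) in the family size
#'
#' Derivative d E(G_i) / d n_i of the gamma-extended continuous expression,
#' evaluated by high-accuracy central differencing of the continuous
#' extension. This is the allocation criterion of a gradient-based
#' (automatic-differentiation) implementation; at integer points it tracks
#' the discrete marginal gain closely but is not bitwise identical to it.
#'
#' @inheritParams marginal_gain
#' @param n Current family sizes; real values are permitted.
#' @return Numeric vector of per-cross gain rates (positive).
#' @export
continuous_gradient <- function(cross_set, n, scenario) {
  cs <- as_cross_set(cross_set)
  s <- ca_scenario_s(scenario, nrow(cs))
  if (length(n) != nrow(cs) || any(n < s))
    ca_stop_validation("'n' must supply one value per cross, n_i >= s_i")
  H <- sqrt(scenario$H2)
  vapply(seq_len(nrow(cs)), function(i) {
    H * sqrt(cs$seg_var[i]) * ca_std_top_grad(n[i], s[i])
  }, 0)
}

#' Greedy optimal allocation of progeny to crosses
#'
#' Starts from the feasible minimum `n_i = s_i` and assigns each of the
#' remaining `N - sum(s)` individuals, one at a time, to the cross with the
#' currently largest allocation criterion; only that cross's criterion is
#' then updated. Because every E(G_i) is increasing and concave in `n_i`,
#' the greedy path attains the global maximum of E(G) over all integer
#' allocations with `sum(n) = N`, `n_i >= s_i`.
#'
#' The criterion is the `v_i`-weighted per-cross gain, so the algorithm
#' maximizes the total E(G) also when `s` varies across crosses (with
#' constant `s` the weights are equal and irrelevant). Ties break in favour
#' of the lowest cross index (input order).
#'
#' @inheritParams marginal_gain
#' @param criterion `"discrete"` (forward difference of E(G_i), the
#'   normative criterion backed by the optimality argument) or
#'   `"continuous"` (gradient of the continuous extension evaluated at the
#'   current integer point, as a gradient-ascent implementation would use).
#' @param keep_trace Record the per-iteration choices.
#' @return An [allocation()] object; when `keep_trace = TRUE` it carries an
#'   attribute `"trace"`, a data frame with columns `iteration`, `cross_id`,
#'   `gain` (unweighted E(G_i) marginal gain of the chosen cross at the
#'   moment of assignment) and `n_after`.
#' @examples
#' cs <- cross_set(c(90, 90), c(1, 9))
#' greedy_allocate(cs, scenario(N = 20, s = 2, H2 = 0.9))
#' @export
greedy_allocate <- function(cross_set, scenario,
                            criterion = c("discrete", "continuous"),
                            keep_trace = FALSE) {
  criterion <- match.arg(criterion)
  cs <- as_cross_set(cross_set)
  k <- nrow(cs)
  s <- ca_scenario_s(scenario, k)
  H <- sqrt(scenario$H2)
  v <- s / sum(s)
  ss <- sqrt(cs$seg_var)
  n <- s
  m <- scenario$N - sum(s)
  crit_of <- if (criterion == "discrete") {
    function(i) ca_std_top_mean(n[i] + 1L, s[i]) - ca_std_top_mean(n[i], s[i])
  } else {
    function(i) ca_std_top_grad(n[i], s[i])
  }
  crit <- v * H * ss * vapply(seq_len(k), crit_of, 0)
  tr_id <- integer(m); tr_gain <- numeric(m); tr_n <- integer(m)
  for (it in seq_len(m)) {
    i <- which.max(crit)  # which.max takes the first maximum: lowest index
    if (keep_trace) {
      tr_id[it] <- i
      tr_gain[it] <- H * ss[i] *
        (ca_std_top_mean(n[i] + 1L, s[i]) - ca_std_top_mean(n[i], s[i]))
    }
    n[i] <- n[i] + 1L
    crit[i] <- v[i] * H * ss[i] * crit_of(i)
    if (keep_trace) tr_n[it] <- n[i]
  }
  out <- allocation(cs, n, scenario)
  if (keep_trace)
    attr(out, "trace") <- data.frame(iteration = seq_len(m),
                                     cross_id = cs$id[tr_id],
                                     gain = tr_gain, n_after = tr_n,
                                     stringsAsFactors = FALSE)
  out
}

#' Exhaustive optimal allocation (oracle)
#'
#' Enumerates every integer allocation with `n_i >= s_i` and
#' `sum(n) = N` and returns the one maximizing E(G). Intended as an
#' optimality oracle for small instances; refuses instances whose
#' composition count exceeds `max_compositions`.
#'
#' @inheritParams marginal_gain
#' @param max_compositions Upper bound on the number of feasible
#'   allocations that will be enumerated.
#' @return An [allocation()] object attaining the exhaustive maximum.
#' @export
brute_force_allocate <- function(cross_set, scenario,
                                 max_compositions = 2e6) {
  cs <- as_cross_set(cross_set)
  k <- nrow(cs)
  s <- ca_scenario_s(scenario, k)
  m <- scenario$N - sum(s)
  n_comp <- choose(m + k - 1, k - 1)
  if (n_comp > max_compositions)
    ca_stop_validation("instance too large for exhaustive search: ",
                       format(n_comp, big.mark = ","),
                       " feasible allocations exceed the limit of ",
                       format(max_compositions, big.mark = ","))
  H <- sqrt(scenario$H2)
  v <- s / sum(s)
  ss <- sqrt(cs$seg_var)
  # per-cross objective contribution v_i * H * sigma*_i * d(s_i + e, s_i)
  # for every feasible extra e = 0..m, precomputed once
  contrib <- lapply(seq_len(k), function(i) {
    vapply(0:m, function(e) {
      v[i] * (cs$mu[i] + H * ss[i] * ca_std_top_mean(s[i] + e, s[i]))
    }, 0)
  })
  best <- -Inf
  best_extra <- integer(k)
  extra <- integer(k)
  recurse <- function(i, left, acc) {
    if (i == k) {
      val <- acc + contrib[[k]][left + 1]
      if (val > best) {
        extra[k] <<- left
        best <<- val
        best_extra <<- extra
      }
      return(invisible(NULL))
    }
    for (e in 0:left) {
      extra[i] <<- e
      recurse(i + 1, left - e, acc + contrib[[i]][e + 1])
    }
  }
  recurse(1, m, 0)
  allocation(cs, s + best_extra, scenario)
}

#' Regression of optimal family sizes on segregation standard deviations
#'
#' Ordinary least squares of the allocated family sizes `n_i` on the
#' segregation standard deviations `sigma*_i`. The optimal allocation is
#' approximately linear in `sigma*`, with intercept and slope specific to
#' the data set, `N` and `s`; the fitted line gives a quick readout of how
#' many individuals a cross of given `sigma*` receives.
#'
#' @param allocation An [allocation()] object (or an integer vector of
#'   family sizes).
#' @param cross_set The corresponding [cross_set()]; defaults to the
#'   crosses stored in the allocation.
#' @return An object of class `sigma_regression`: list with `intercept`
#'   (individuals), `slope` (individuals per trait-unit of sigma*),
#'   `fitted` per-cross values and the underlying `lm` fit.
#' @examples
#' cs <- barley_crosses()
#' opt <- greedy_allocate(cs, scenario(400, 5, 0.9))
#' reg <- allocation_sigma_regression(opt)
#' predict(reg, sigma_star = c(1.5, 3))
#' @export
allocation_sigma_regression <- function(allocation, cross_set = NULL) {
  if (inherits(allocation, "allocation")) {
    n <- allocation$table$n
    if (is.null(cross_set))
      cross_set <- cross_set(allocation$table$mu, allocation$table$seg_var,
                             id = allocation$table$id)
  } else {
    n <- allocation
    if (is.null(cross_set))
      ca_stop_validation("'cross_set' is required when 'allocation' is a ",
                         "bare family-size vector")
  }
  cs <- as_cross_set(cross_set)
  if (nrow(cs) < 3)
    ca_stop_validation("regression needs at least 3 crosses")
  sigma_star <- sqrt(cs$seg_var)
  if (stats::var(sigma_star) == 0)
    ca_stop_validation("regression undefined: all sigma* are equal")
  fit <- stats::lm(n ~ sigma_star, data = data.frame(n = n,
                                                     sigma_star = sigma_star))
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 fitted = stats::setNames(unname(stats::fitted(fit)), cs$id),
                 model = fit),
            class = "sigma_regression")
}

#' Predict family sizes from a sigma* regression
#'
#' @param object A `sigma_regression` from [allocation_sigma_regression()].
#' @param sigma_star Segregation standard deviations at which to predict.
#' @param round Round to the nearest whole individual (default), matching
#'   the integer nature of family sizes.
#' @param ... Unused.
#' @return Predicted family sizes.
#' @export
predict.sigma_regression <- function(object, sigma_star, round = TRUE, ...) {
  p <- object$intercept + object$slope * sigma_star
  if (round) round(p) else p
}

#' @export
print.sigma_regression <- function(x, ...) {
  cat(sprintf("n_i ~ %.4f + %.4f * sigma*_i\n", x$intercept, x$slope))
  invisible(x)
}
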