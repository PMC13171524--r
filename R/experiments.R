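#' @importFrom stats quantile sd setNames aggregate
NULL

# constant-family-size arm: floor(N/k) everywhere, remainder to the first
# N mod k crosses (totals must match N; the canonical grids use divisible
# cases where this reduces to N/k exactly)
ca_constant_n <- function(N, k) {
  n <- rep(N %/% k, k)
  rem <- N %% k
  if (rem > 0) n[seq_len(rem)] <- n[seq_len(rem)] + 1L
  as.integer(n)
}

#' Compare constant and optimal family sizes over a scenario grid
#'
#' For every combination of `N`, `H2` and `s`, computes E(G) under the
#' constant allocation `n_i = N/k` and under the greedy-optimal allocation,
#' and their difference. By the optimality of the greedy path the
#' difference is non-negative in every cell.
#'
#' @param cross_set A [cross_set()].
#' @param N,H2,s Vectors spanning the grid (defaults: the canonical
#'   experiment grid `N` in 400/1200, `H2` in 0.7/0.9, `s` in 1..5, 10).
#' @param criterion Allocation criterion passed to [greedy_allocate()].
#' @return Data frame with one row per grid cell: `N`, `H2`, `s`,
#'   `EG_const`, `EG_opt`, `delta`, `feasible`. Infeasible cells (constant
#'   arm below `s`) are flagged, not dropped.
#' @examples
#' compare_constant_vs_optimal(barley_crosses(), N = 400, H2 = 0.9, s = 5)
#' @export
compare_constant_vs_optimal <- function(cross_set,
                                        N = c(400L, 1200L),
                                        H2 = c(0.7, 0.9),
                                        s = c(1L, 2L, 3L, 4L, 5L, 10L),
                                        criterion = "discrete") {
  cs <- as_cross_set(cross_set)
  k <- nrow(cs)
  grid <- expand.grid(N = N, H2 = H2, s = s,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$N, grid$H2, grid$s), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    ncon <- ca_constant_n(g$N, k)
    if (g$N < k * g$s || any(ncon < g$s))
      return(data.frame(g, EG_const = NA_real_, EG_opt = NA_real_,
                        delta = NA_real_, feasible = FALSE))
    scn <- scenario(g$N, g$s, g$H2)
    eg_c <- allocation(cs, ncon, scn)$totals$EG
    eg_o <- greedy_allocate(cs, scn, criterion = criterion)$totals$EG
    data.frame(g, EG_const = eg_c, EG_opt = eg_o, delta = eg_o - eg_c,
               feasible = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of the optimization to variance prediction error
#'
#' Per replicate, the segregation variances are perturbed with prediction
#' error of a given MAVE level ([add_variance_noise()]), family sizes are
#' optimized on the noisy variances, and the resulting (suboptimal)
#' allocation is evaluated under the TRUE parameters. The loss relative to
#' the true optimum is `delta_var = EG_optimal - EG_suboptimal`, the margin
#' over the constant allocation is `delta_const = EG_const - EG_suboptimal`
#' (negative when the noisy-optimal allocation still beats constant family
#' sizes), and the percentage loss expresses `delta_var` as a share of the
#' original difference `EG_optimal - EG_const`.
#'
#' @param cross_set A [cross_set()] holding the true parameters.
#' @param mave MAVE levels as fractions of the true variances.
#' @param N,H2,s Scenario grid (defaults as in
#'   [compare_constant_vs_optimal()]).
#' @param replicates Replicates per (MAVE, scenario) cell.
#' @param seed Master seed; per-replicate sub-seeds are spawned from it and
#'   recorded in the output.
#' @param criterion Allocation criterion for [greedy_allocate()].
#' @return List with `replicates` (one row per replicate with `delta_var`,
#'   `delta_const`, `pct_loss`, `rep_seed`) and `summary` (per cell: mean
#'   and 5th/95th percentiles of `delta_var`, mean `delta_const`, mean
#'   `pct_loss`, replicate count).
#' @export
variance_error_experiment <- function(cross_set,
                                      mave = c(0.05, 0.10, 0.25),
                                      N = c(400L, 1200L),
                                      H2 = c(0.7, 0.9),
                                      s = c(1L, 2L, 3L, 4L, 5L, 10L),
                                      replicates = 100, seed = 1,
                                      criterion = "discrete") {
  cs <- as_cross_set(cross_set)
  k <- nrow(cs)
  grid <- expand.grid(mave = mave, N = N, H2 = H2, s = s,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$mave, grid$N, grid$H2, grid$s), , drop = FALSE]
  set.seed(as.integer(seed))
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 nrow(grid) * replicates),
                      nrow = nrow(grid))
  reps <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    scn <- scenario(g$N, g$s, g$H2)
    eg_opt <- greedy_allocate(cs, scn, criterion = criterion)$totals$EG
    eg_con <- allocation(cs, ca_constant_n(g$N, k), scn)$totals$EG
    dv <- dc <- numeric(replicates)
    for (r in seq_len(replicates)) {
      noisy <- add_variance_noise(cs, g$mave, seed = rep_seeds[i, r])
      n_sub <- greedy_allocate(noisy, scn, criterion = criterion)$table$n
      eg_sub <- allocation(cs, n_sub, scn)$totals$EG
      dv[r] <- eg_opt - eg_sub
      dc[r] <- eg_con - eg_sub
    }
    reps[[i]] <- data.frame(g, replicate = seq_len(replicates),
                            rep_seed = rep_seeds[i, ],
                            delta_var = dv, delta_const = dc,
                            pct_loss = 100 * dv / (eg_opt - eg_con),
                            row.names = NULL)
  }
  reps <- do.call(rbind, reps)
  summary <- aggregate(cbind(mean_delta_var = delta_var) ~ mave + N + H2 + s,
                       data = reps, FUN = mean)
  summary$q5_delta_var <- aggregate(delta_var ~ mave + N + H2 + s,
                                    data = reps,
                                    FUN = function(x) quantile(x, 0.05))$delta_var
  summary$q95_delta_var <- aggregate(delta_var ~ mave + N + H2 + s,
                                     data = reps,
                                     FUN = function(x) quantile(x, 0.95))$delta_var
  summary$mean_delta_const <- aggregate(delta_const ~ mave + N + H2 + s,
                                        data = reps, FUN = mean)$delta_const
  summary$mean_pct_loss <- aggregate(pct_loss ~ mave + N + H2 + s,
                                     data = reps, FUN = mean)$pct_loss
  summary$replicates <- replicates
  list(replicates = reps, summary = summary)
}

#' Sensitivity of E(Y) predictions to non-normal trait distributions
#'
#' Per replicate, `k` crosses' trait samples are drawn from a non-normal
#' family ([sample_non_normal_population()]); per cross the sample mean and
#' SD are plugged into the normal order-statistics formula to predict the
#' mean of the selected fraction, the actual top `s` values per cross are
#' pooled, and the signed percentage difference of the observed pooled mean
#' versus the prediction is recorded. Under truly normal samples the
#' differences are centered on zero; skewed or heavy-tailed samples lead
#' the normal formula to underestimate, a bimodal mixture to overestimate.
#'
#' @param families Distribution families to test.
#' @param n Family sizes to test.
#' @param k Crosses per replicate.
#' @param s Selected per cross.
#' @param replicates Replicates per (family, n) cell.
#' @param center Common mean of all samples (trait units).
#' @param seed Master seed; sub-seeds recorded in the output.
#' @return List with `replicates` (per replicate `pct_diff`) and `summary`
#'   (per family and n: mean, SD and standard error of `pct_diff`).
#' @export
normality_experiment <- function(families = c("skew_t", "heavy_t", "bimodal"),
                                 n = c(20L, 60L, 100L),
                                 k = 10, s = 5, replicates = 100,
                                 center = 92, seed = 1) {
  grid <- expand.grid(family = families, n = n,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 nrow(grid) * replicates),
                      nrow = nrow(grid))
  reps <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pct <- numeric(replicates)
    for (r in seq_len(replicates)) {
      set.seed(rep_seeds[i, r])
      pred <- obs <- numeric(k)
      for (j in seq_len(k)) {
        x <- sample_non_normal_population(g$n, g$family, center = center)
        pred[j] <- top_fraction_expectation(mean(x), sd(x), g$n, s)
        obs[j] <- mean(sort(x, decreasing = TRUE)[seq_len(s)])
      }
      # constant s => equal selected-fraction weights over crosses
      pct[r] <- 100 * (mean(obs) - mean(pred)) / mean(pred)
    }
    reps[[i]] <- data.frame(g, replicate = seq_len(replicates),
                            rep_seed = rep_seeds[i, ], pct_diff = pct,
                            row.names = NULL)
  }
  reps <- do.call(rbind, reps)
  summary <- aggregate(pct_diff ~ family + n, data = reps, FUN = mean)
  names(summary)[names(summary) == "pct_diff"] <- "mean_pct_diff"
  summary$sd_pct_diff <- aggregate(pct_diff ~ family + n, data = reps,
                                   FUN = sd)$pct_diff
  summary$se_pct_diff <- summary$sd_pct_diff / sqrt(replicates)
  summary$replicates <- replicates
  list(replicates = reps, summary = summary)
}

#' Variance of the top order statistic as a function of family size
#'
#' Tabulates Var(max of n) for a grid of segregation standard deviations
#' and family sizes. The variance scales with `sigma^2` and decreases in
#' `n`: growing a family shrinks the uncertainty of its best line, the
#' faster the larger its segregation variance.
#'
#' @param sigma Standard deviations (positive).
#' @param n Family sizes (integers >= 1).
#' @return Data frame with columns `sigma`, `n`, `var_max`.
#' @examples
#' order_stat_variance_curves(sigma = c(0.5, 4), n = c(1, 10, 100))
#' @export
order_stat_variance_curves <- function(sigma = c(0.5, 1, 2, 4),
                                       n = seq(1L, 100L)) {
  if (any(sigma <= 0)) ca_stop_validation("'sigma' must be positive")
  if (any(n < 1) || any(n != round(n)))
    ca_stop_validation("'n' must contain integers >= 1")
  std_var <- vapply(n, function(ni) {
    ca_std_moment(ni, ni, 2L) - ca_std_moment(ni, ni, 1L)^2
  }, 0)
  out <- expand.grid(n = as.integer(n), sigma = sigma,
                     KEEP.OUT.ATTRS = FALSE)
  out$var_max <- rep(std_var, times = length(sigma)) *
    rep(sigma^2, each = length(n))
  out[c("sigma", "n", "var_max")]
}
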