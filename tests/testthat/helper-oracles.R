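# Monte-Carlo oracles for order-statistic moments, independent of the
# quadrature path they check. reps x n normal draws; column-sorted.

mc_order_stat <- function(n, r, reps = 2e5, mean = 0, sd = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(reps * n, mean, sd), nrow = reps)
  vals <- apply(x, 1, function(row) sort(row)[r])
  list(mean = mean(vals), var = var(vals),
       se_mean = sd(vals) / sqrt(reps),
       se_var = sd((vals - mean(vals))^2) / sqrt(reps))
}

mc_top_mean <- function(n, s, reps = 2e5, mean = 0, sd = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(reps * n, mean, sd), nrow = reps)
  vals <- apply(x, 1, function(row) mean(sort(row, decreasing = TRUE)[1:s]))
  list(mean = mean(vals), se_mean = sd(vals) / sqrt(reps))
}

# full selection-experiment oracle: draw phenotypes for every cross,
# truncate the top s_i per cross, average genotypic gain via H2 shrinkage
mc_selection_experiment <- function(cs, n, s, H2, reps = 2e4, seed = 1) {
  set.seed(seed)
  k <- nrow(cs)
  sigma <- sqrt(cs$seg_var / H2)
  EY_i <- matrix(0, reps, k)
  for (i in seq_len(k)) {
    x <- matrix(rnorm(reps * n[i], cs$mu[i], sigma[i]), nrow = reps)
    EY_i[, i] <- apply(x, 1, function(row)
      mean(sort(row, decreasing = TRUE)[1:s[i]]))
  }
  v <- s / sum(s)
  EY <- EY_i %*% v
  EG_i <- sweep(H2 * EY_i, 2, (1 - H2) * cs$mu, "+")
  EG <- EG_i %*% v
  list(EY = mean(EY), se_EY = sd(EY) / sqrt(reps),
       EG = mean(EG), se_EG = sd(EG) / sqrt(reps))
}

toy_two_crosses <- function() cross_set(mu = c(90, 90), seg_var = c(1, 9),
                                        id = c("low", "high"))
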