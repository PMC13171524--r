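# Greedy allocation, the exhaustive-search oracle, and the family-size
# regression on sigma*.

test_that("discrete marginal gains are positive, decreasing and sigma*-linear", {
  scn <- scenario(100, 2, 0.81)
  cs <- toy_two_crosses()
  g_lo <- marginal_gain(cs, c(2, 2), scn)
  g_hi <- marginal_gain(cs, c(12, 12), scn)
  expect_true(all(g_lo > 0) && all(g_hi > 0))
  expect_true(all(g_hi < g_lo))
  # sigma* = 3 vs 1 => triple the gain at equal (n, s, H2)
  expect_equal(g_lo[2], 3 * g_lo[1], tolerance = 1e-9)
  # frozen oracle: gain at n = 1, s = 1, H2 = 1 is E[max of 2] - E[single]
  g1 <- marginal_gain(cross_set(0, 1), 1, scenario(1, 1, 1))
  expect_equal(g1, 1 / sqrt(pi), tolerance = 1e-8)
})

test_that("the continuous gradient is positive and tracks the discrete gain", {
  cs <- cross_set(c(90, 90, 90), c(1, 4, 16))
  scn <- scenario(600, 5, 0.9)
  for (n in c(5, 20, 100, 200)) {
    grad <- continuous_gradient(cs, rep(n, 3), scn)
    expect_true(all(grad > 0), label = paste("positive gradient at n =", n))
    expect_equal(grad[2], 2 * grad[1], tolerance = 1e-6)
    disc <- marginal_gain(cs, rep(n, 3), scn)
    # concavity brackets the gradient between adjacent forward differences
    expect_true(all(grad >= disc - 1e-10),
                label = paste("gradient >= forward difference at n =", n))
  }
})

test_that("greedy allocation handles degenerate and symmetric cases", {
  # single cross takes everything
  a1 <- greedy_allocate(cross_set(90, 4), scenario(37, 3, 0.9))
  expect_equal(a1$table$n, 37)
  # identical crosses split evenly
  cs <- cross_set(c(90, 90), c(4, 4))
  a2 <- greedy_allocate(cs, scenario(24, 2, 0.9))
  expect_equal(sort(a2$table$n), c(12, 12))
  # infeasible N
  expect_error(greedy_allocate(cs, scenario(3, 2, 0.9)),
               class = "crossalloc_validation_error")
  # ties break to the lowest input index
  a3 <- greedy_allocate(cs, scenario(5, 2, 0.9))
  expect_equal(a3$table$n, c(3, 2))
})

test_that("greedy equals exhaustive search on the reference instance", {
  cs <- cross_set(c(90, 90), c(1, 9))
  scn <- scenario(12, 2, 0.9)
  gr <- greedy_allocate(cs, scn)
  bf <- brute_force_allocate(cs, scn)
  expect_equal(gr$table$n, bf$table$n)
  expect_equal(gr$totals$EG, bf$totals$EG, tolerance = 1e-12)
})

test_that("greedy attains the exhaustive optimum on random small instances", {
  set.seed(481)
  for (i in 1:40) {
    k <- sample(2:3, 1)
    s <- sample(1:3, 1)
    N <- sum(rep(s, k)) + sample(0:15, 1)
    cs <- cross_set(runif(k, 80, 100), runif(k, 0.5, 16))
    scn <- scenario(N, s, sample(c(0.7, 0.9, 1), 1))
    gr <- greedy_allocate(cs, scn)
    bf <- brute_force_allocate(cs, scn)
    expect_equal(gr$totals$EG, bf$totals$EG, tolerance = 1e-9,
                 label = sprintf("instance %d (k=%d, N=%d, s=%d)", i, k, N, s))
  }
})

test_that("greedy handles per-cross selected counts (variable s)", {
  set.seed(77)
  for (i in 1:10) {
    k <- 3
    s <- sample(1:3, k, replace = TRUE)
    N <- sum(s) + sample(3:12, 1)
    cs <- cross_set(runif(k, 80, 100), runif(k, 0.5, 16))
    scn <- scenario(N, s, 0.9)
    gr <- greedy_allocate(cs, scn)
    bf <- brute_force_allocate(cs, scn)
    expect_equal(gr$totals$EG, bf$totals$EG, tolerance = 1e-9)
    expect_true(all(gr$table$n >= s))
  }
})

test_that("brute force refuses oversized instances with a size estimate", {
  cs <- cross_set(runif(10, 80, 100), runif(10, 1, 9))
  expect_error(brute_force_allocate(cs, scenario(500, 5, 0.9)),
               "feasible allocations",
               class = "crossalloc_validation_error")
})

test_that("greedy dominates the constant allocation", {
  b <- barley_crosses()
  for (scn in list(scenario(400, 5, 0.9), scenario(400, 10, 0.7))) {
    opt <- greedy_allocate(b, scn)$totals$EG
    const <- allocation(b, rep(scn$N / 20, 20), scn)$totals$EG
    expect_gt(opt, const)
  }
  # identical crosses: no gain over constant
  same <- cross_set(rep(90, 4), rep(4, 4))
  scn <- scenario(40, 2, 0.9)
  expect_equal(greedy_allocate(same, scn)$totals$EG,
               allocation(same, rep(10, 4), scn)$totals$EG,
               tolerance = 1e-12)
})

test_that("the allocation is independent of the cross means", {
  set.seed(90125)
  b <- barley_crosses()
  scn <- scenario(400, 5, 0.9)
  n0 <- greedy_allocate(b, scn)$table$n
  perm <- sample(20)
  bp <- cross_set(b$mu[perm], b$seg_var, id = b$id)
  expect_equal(greedy_allocate(bp, scn)$table$n, n0)
})

test_that("the allocation trace is valid", {
  b <- barley_crosses()
  scn <- scenario(100, 2, 0.9)
  a <- greedy_allocate(b, scn, keep_trace = TRUE)
  tr <- attr(a, "trace")
  expect_equal(nrow(tr), 100 - 20 * 2)
  expect_equal(tr$iteration, seq_len(nrow(tr)))
  # replaying the trace reproduces the final allocation
  n_replay <- rep(2L, 20)
  for (id in tr$cross_id) {
    i <- match(id, b$id)
    n_replay[i] <- n_replay[i] + 1L
  }
  expect_equal(n_replay, a$table$n)
  # per-cross gains never increase along the trace (concavity)
  for (id in unique(tr$cross_id)) {
    g <- tr$gain[tr$cross_id == id]
    expect_true(all(diff(g) <= 1e-12), label = paste("gains for", id))
  }
})

test_that("discrete and continuous criteria agree up to near-ties", {
  # the two criteria may swap individuals between near-tied crosses; their
  # objective values must agree to the tie tolerance even when the integer
  # vectors differ (warning-level check, not an assertion of identity)
  b <- barley_crosses()
  scn <- scenario(400, 5, 0.9)
  ad <- greedy_allocate(b, scn, criterion = "discrete")
  ac <- greedy_allocate(b, scn, criterion = "continuous")
  if (!identical(ad$table$n, ac$table$n)) {
    diffs <- which(ad$table$n != ac$table$n)
    warning("criteria allocations differ for crosses: ",
            paste(b$id[diffs], collapse = ", "))
  }
  expect_equal(ac$totals$EG, ad$totals$EG, tolerance = 1e-5)
  expect_lte(ac$totals$EG, ad$totals$EG + 1e-12)
})

test_that("the sigma* regression recovers exact linear allocations", {
  sv <- c(1, 2.25, 4, 9)
  cs <- cross_set(rep(90, 4), sv)
  n <- 5 + 4 * sqrt(sv)  # exactly linear in sigma*
  reg <- allocation_sigma_regression(n, cs)
  expect_equal(reg$intercept, 5, tolerance = 1e-9)
  expect_equal(reg$slope, 4, tolerance = 1e-9)
  expect_equal(sum(n - reg$fitted), 0, tolerance = 1e-9)
  expect_equal(predict(reg, 2, round = FALSE), 13, tolerance = 1e-9)
  # degenerate sigma*
  expect_error(
    allocation_sigma_regression(c(5, 5, 5), cross_set(rep(90, 3), rep(4, 3))),
    class = "crossalloc_validation_error")
  expect_error(
    allocation_sigma_regression(c(5, 5), cross_set(c(90, 91), c(1, 4))),
    class = "crossalloc_validation_error")
})
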