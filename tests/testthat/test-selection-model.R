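# The mixture model of the base population and the selection-response
# decomposition E(X), E(Y), S, R, E(G).

test_that("cross sets validate their invariants", {
  expect_error(cross_set(numeric(0), numeric(0)),
               class = "crossalloc_validation_error")
  expect_error(cross_set(c(90, 91), c(1, -1)),
               class = "crossalloc_validation_error")
  expect_error(cross_set(c(90, 91), c(1, 2), id = c("a", "a")),
               class = "crossalloc_validation_error")
  expect_error(cross_set(c(90, Inf), c(1, 2)),
               class = "crossalloc_validation_error")
  cs <- cross_set(c(90, 91), c(1, 2))
  expect_s3_class(cs, "cross_set")
  expect_identical(cs$id, c("cross_1", "cross_2"))
  # data-frame coercion, incl. the 'mean' alias used by the CSV schema
  df <- data.frame(cross_id = "x", mean = 90, seg_var = 4)
  expect_equal(as_cross_set(df)$mu, 90)
})

test_that("scenarios validate and expand per-cross selected counts", {
  expect_error(scenario(100, 0, 0.9), class = "crossalloc_validation_error")
  expect_error(scenario(100, 5, 0), class = "crossalloc_validation_error")
  expect_error(scenario(100, 5, 1.1), class = "crossalloc_validation_error")
  expect_error(scenario(10.5, 5, 0.9), class = "crossalloc_validation_error")
  # N < sum(s) is caught at use
  expect_error(allocation(toy_two_crosses(), c(5, 5),
                          scenario(10, c(5, 6), 0.9)),
               class = "crossalloc_validation_error")
})

test_that("phenotypic SD follows seg_var / H2", {
  expect_equal(phenotypic_sd(1, 1), 1)
  expect_equal(phenotypic_sd(4, 0.25), 4)
  expect_equal(phenotypic_sd(8.73, 0.9), sqrt(8.73 / 0.9), tolerance = 1e-10)
  expect_equal(round(phenotypic_sd(8.73, 0.9), 4), 3.1145)
  expect_error(phenotypic_sd(0, 0.9), class = "crossalloc_validation_error")
})

test_that("base expectation is the mixture mean", {
  cs <- cross_set(c(80, 100), c(1, 1))
  expect_equal(base_expectation(cs, c(10, 10)), 90)
  expect_equal(base_expectation(cs, c(30, 10)), 85)
  expect_equal(base_expectation(cross_set(87.3, 2), 7), 87.3)
  b <- barley_crosses()
  expect_equal(base_expectation(b, rep(20, 20)), 88.6145, tolerance = 1e-10)
})

test_that("selected-fraction expectation reduces to the order-stat oracle", {
  cs1 <- cross_set(0, 1)
  expect_equal(
    selected_fraction_expectation(cs1, 2, scenario(2, 1, 1)),
    1 / sqrt(pi), tolerance = 1e-8)
  # s = n: no within-cross selection
  cs <- toy_two_crosses()
  scn <- scenario(8, 4, 0.9)
  expect_equal(selected_fraction_expectation(cs, c(4, 4), scn), 90,
               tolerance = 1e-9)
  # vanishing segregation variance: E(Y) -> weighted mu
  cs_small <- cross_set(c(90, 95), c(1e-12, 1e-12))
  expect_equal(
    selected_fraction_expectation(cs_small, c(10, 10), scenario(20, 2, 0.9)),
    92.5, tolerance = 1e-5)
  expect_error(allocation(cs, c(3, 5), scenario(8, 4, 0.9)),
               class = "crossalloc_validation_error")
})

test_that("S and R decompose as E(Y) - E(X) and H2 * S", {
  cs <- toy_two_crosses()
  no_sel <- response_to_selection(cs, c(4, 4), scenario(8, 4, 0.9))
  expect_equal(unname(no_sel), c(0, 0, 0), tolerance = 1e-9)
  r1 <- response_to_selection(cross_set(0, 1), 2, scenario(2, 1, 1))
  expect_equal(unname(r1["R"]), 1 / sqrt(pi), tolerance = 1e-8)
  # R is linear in H2 once the phenotypic scale is held fixed: with
  # seg_var scaled as H2 * const the sd is constant, so S is constant
  s_at <- function(H2) response_to_selection(
    cross_set(c(90, 90), H2 * c(4, 4)), c(10, 10),
    scenario(20, 2, H2))[["S"]]
  expect_equal(s_at(0.5), s_at(1), tolerance = 1e-9)
  expect_equal(0.5 * s_at(0.5), response_to_selection(
    cross_set(c(90, 90), 0.5 * c(4, 4)), c(10, 10),
    scenario(20, 2, 0.5))[["R"]] , tolerance = 1e-9)
  # R >= 0 always
  a <- allocation(barley_crosses(), rep(20, 20), scenario(400, 5, 0.7))
  expect_gt(a$totals$R, 0)
})

test_that("expected genetic values exceed the cross means and scale in sigma*", {
  cs <- toy_two_crosses()
  scn <- scenario(20, 2, 0.81)
  g <- expected_genetic_value(cs, c(10, 10), scn)
  expect_true(all(g$per_cross >= cs$mu))
  expect_equal(g$total, mean(g$per_cross))
  # gain R_i = H * sigma* * d(n, s): doubling sigma* doubles the gain
  gain <- function(sv) expected_genetic_value(
    cross_set(90, sv), 10, scenario(10, 2, 0.81))$total - 90
  expect_equal(gain(4), 2 * gain(1), tolerance = 1e-9)
  # s = n leaves E(G_i) = mu_i
  g0 <- expected_genetic_value(cs, c(4, 4), scenario(8, 4, 0.9))
  expect_equal(unname(g0$per_cross), cs$mu, tolerance = 1e-9)
})

test_that("E(Y) and E(G) match a brute-force selection simulation", {
  cs <- cross_set(c(88, 93, 90), c(6, 1.5, 3))
  n <- c(12, 6, 9); s <- c(3, 3, 3); H2 <- 0.8
  scn <- scenario(sum(n), 3, H2)
  mc <- mc_selection_experiment(cs, n, s, H2, reps = 2e4, seed = 99)
  a <- allocation(cs, n, scn)
  expect_lt(abs(a$totals$EY - mc$EY), 3 * mc$se_EY)
  expect_lt(abs(a$totals$EG - mc$EG), 3 * mc$se_EG)
})

test_that("the within-cross response is invariant under permutation of the means", {
  # R_within = H2 * mean(E(Y_i) - mu_i) and E(G) depend only on which
  # seg_var each n_i is attached to, not on the mu pairing (the mixture
  # base mean E(X), and hence S, does shift when unequal n_i meet permuted
  # mu_i)
  set.seed(1203)
  b <- barley_crosses()
  scn <- scenario(400, 5, 0.9)
  n <- greedy_allocate(b, scn)$table$n
  r0 <- response_to_selection(b, n, scn)[["R_within"]]
  eg0 <- expected_genetic_value(b, n, scn)$total
  for (i in 1:5) {
    perm <- sample(20)
    bp <- cross_set(b$mu[perm], b$seg_var, id = b$id)
    expect_equal(response_to_selection(bp, n, scn)[["R_within"]], r0,
                 tolerance = 1e-9)
    expect_equal(expected_genetic_value(bp, n, scn)$total, eg0,
                 tolerance = 1e-9)
  }
})

test_that("E(G_i) is increasing and concave in the family size", {
  grid <- expand.grid(sv = c(0.96, 4, 15.2), s = c(1, 5), H2 = c(0.7, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    eg <- vapply(g$s:120, function(n) expected_genetic_value(
      cross_set(90, g$sv), n, scenario(n, g$s, g$H2))$total, 0)
    d1 <- diff(eg)
    expect_true(all(d1 > 0),
                label = sprintf("monotone (sv=%g s=%g H2=%g)", g$sv, g$s, g$H2))
    expect_true(all(diff(d1) <= 1e-12),
                label = sprintf("concave (sv=%g s=%g H2=%g)", g$sv, g$s, g$H2))
  }
})
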