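#' Construct a cross set
#'
#' A cross set holds, for each of k crosses of homozygous parents, the
#' predicted mean `mu` of its inbred (e.g. doubled haploid) offspring and
#' the predicted segregation variance `seg_var` generated by segregation of
#' the parental alleles. Both are typically predicted from parental marker
#' data and treated as known here.
#'
#' @param mu Numeric vector of predicted cross means (trait units).
#' @param seg_var Numeric vector of predicted segregation variances
#'   (squared trait units), strictly positive.
#' @param id Optional character labels, unique; defaults to `cross_1..k`.
#' @param parent1,parent2 Optional parent names.
#' @return An object of class `cross_set`: a data frame with columns
#'   `id`, `parent1`, `parent2`, `mu`, `seg_var`, one row per cross, in
#'   input order (the allocator breaks ties by this order).
#' @examples
#' cs <- cross_set(mu = c(90, 95), seg_var = c(9, 1), id = c("A", "B"))
#' @export
cross_set <- function(mu, seg_var, id = NULL, parent1 = NULL, parent2 = NULL) {
  k <- length(mu)
  if (k < 1) ca_stop_validation("a cross set needs at least one cross")
  if (length(seg_var) != k)
    ca_stop_validation("'mu' and 'seg_var' must have equal length")
  if (is.null(id)) id <- paste0("cross_", seq_len(k))
  if (anyDuplicated(id))
    ca_stop_validation("cross ids must be unique")
  if (any(!is.finite(mu)))
    ca_stop_validation("all cross means must be finite")
  if (any(!is.finite(seg_var)) || any(seg_var <= 0))
    ca_stop_validation("all segregation variances must be positive")
  out <- data.frame(
    id = as.character(id),
    parent1 = if (is.null(parent1)) NA_character_ else as.character(parent1),
    parent2 = if (is.null(parent2)) NA_character_ else as.character(parent2),
    mu = as.numeric(mu),
    seg_var = as.numeric(seg_var),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cross_set", "data.frame")
  out
}

#' Coerce a data frame to a cross set
#'
#' @param x A data frame with columns `mu` and `seg_var` (or `mean` as an
#'   alias for `mu`), optionally `id`/`cross_id`, `parent1`, `parent2`.
#' @return A [cross_set()].
#' @export
as_cross_set <- function(x) {
  if (inherits(x, "cross_set")) return(x)
  nm <- names(x)
  mu <- if ("mu" %in% nm) x$mu else x$mean
  if (is.null(mu)) ca_stop_validation("no 'mu' (or 'mean') column found")
  if (is.null(x$seg_var)) ca_stop_validation("no 'seg_var' column found")
  id <- if ("id" %in% nm) x$id else x$cross_id
  cross_set(mu = mu, seg_var = x$seg_var, id = id,
            parent1 = x$parent1, parent2 = x$parent2)
}

#' @export
print.cross_set <- function(x, ...) {
  cat("Cross set with", nrow(x), "crosses\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Define a selection scenario
#'
#' A scenario fixes the experiment-level parameters of a selection cycle:
#' the total population size `N` to distribute over the crosses, the number
#' of individuals `s` selected per cross, and the heritability `H2` of the
#' field trial in which selection takes place.
#'
#' @param N Total population size (positive integer, `N >= sum(s)` once `s`
#'   is expanded to the number of crosses).
#' @param s Selected per cross: a single positive integer (applied to every
#'   cross) or one value per cross.
#' @param H2 Heritability, in (0, 1]. Phenotypic SD per cross is
#'   `sqrt(seg_var / H2)`, and the realized genetic gain is `H2` times the
#'   selection differential.
#' @return An object of class `scenario`.
#' @examples
#' scenario(N = 400, s = 5, H2 = 0.9)
#' @export
scenario <- function(N, s, H2) {
  if (!is.numeric(N) || length(N) != 1 || N != round(N) || N < 1)
    ca_stop_validation("'N' must be a positive integer")
  if (!is.numeric(s) || any(s != round(s)) || any(s < 1))
    ca_stop_validation("'s' must contain positive integers")
  if (!is.numeric(H2) || length(H2) != 1 || H2 <= 0 || H2 > 1)
    ca_stop_validation("'H2' must lie in (0, 1]")
  structure(list(N = as.integer(N), s = as.integer(s), H2 = as.numeric(H2)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Selection scenario: N =", x$N, "| s =",
      paste(x$s, collapse = ","), "| H2 =", x$H2, "\n")
  invisible(x)
}

# expand per-cross selected counts and validate against k and N
ca_scenario_s <- function(scn, k) {
  s <- scn$s
  if (length(s) == 1) s <- rep(s, k)
  if (length(s) != k)
    ca_stop_validation("'s' must be scalar or one value per cross")
  if (scn$N < sum(s))
    ca_stop_validation("infeasible scenario: N = ", scn$N,
                       " < sum(s) = ", sum(s))
  s
}

#' Phenotypic standard deviation of a cross
#'
#' Selection acts on phenotypes from a trial with heritability `H2`, so the
#' phenotypic variance of a cross is its segregation variance divided by
#' `H2`.
#'
#' @param seg_var Segregation variance(s), positive.
#' @param H2 Heritability in (0, 1].
#' @return `sqrt(seg_var / H2)`, in trait units.
#' @examples
#' phenotypic_sd(4, 0.25)  # 4
#' @export
phenotypic_sd <- function(seg_var, H2) {
  if (any(seg_var <= 0)) ca_stop_validation("'seg_var' must be positive")
  if (H2 <= 0 || H2 > 1) ca_stop_validation("'H2' must lie in (0, 1]")
  sqrt(seg_var / H2)
}

#' Evaluate a family-size allocation
#'
#' Computes the complete decomposition of a selection experiment for a given
#' integer allocation of family sizes: per-cross expected selected-fraction
#' means E(Y_i) and expected genetic values E(G_i), and the totals E(X)
#' (base-population mean), E(Y), the selection differential S = E(Y) - E(X),
#' the response to selection R = H2 * S, and the expected genetic value
#' E(G) of the next cycle.
#'
#' The base population is the mixture of the k family distributions with
#' weights `w_i = n_i / N`; the selected fraction pools the best `s_i` of
#' each family with weights `v_i = s_i / sum(s)`. With constant `s_i` the
#' total E(G) is the unweighted mean of the E(G_i).
#'
#' @param cross_set A [cross_set()].
#' @param n Integer family sizes, one per cross, `n_i >= s_i`,
#'   `sum(n) == N`.
#' @param scenario A [scenario()].
#' @return An object of class `allocation`: list with `table` (per-cross
#'   data frame with columns `id`, `mu`, `seg_var`, `n`, `s`, `w`, `v`,
#'   `EY`, `EG`), `totals` (named list `EX`, `EY`, `S`, `R`, `EG`), and the
#'   `scenario`.
#' @examples
#' cs <- cross_set(c(90, 95), c(9, 1))
#' allocation(cs, n = c(12, 8), scenario(N = 20, s = 2, H2 = 0.9))
#' @export
allocation <- function(cross_set, n, scenario) {
  cs <- as_cross_set(cross_set)
  k <- nrow(cs)
  s <- ca_scenario_s(scenario, k)
  if (length(n) != k)
    ca_stop_validation("'n' must supply one family size per cross")
  if (any(n != round(n)))
    ca_stop_validation("family sizes must be integers")
  n <- as.integer(n)
  if (any(n < s))
    ca_stop_validation("family sizes must satisfy n_i >= s_i")
  if (sum(n) != scenario$N)
    ca_stop_validation("family sizes must sum to N = ", scenario$N,
                       " (got ", sum(n), ")")
  H2 <- scenario$H2
  sigma <- phenotypic_sd(cs$seg_var, H2)
  EY_i <- vapply(seq_len(k),
                 function(i) cs$mu[i] + sigma[i] * ca_std_top_mean(n[i], s[i]),
                 0)
  EG_i <- cs$mu + H2 * (EY_i - cs$mu)
  w <- n / scenario$N
  v <- s / sum(s)
  totals <- list(
    EX = sum(w * cs$mu),
    EY = sum(v * EY_i),
    S = sum(v * EY_i) - sum(w * cs$mu),
    R = H2 * (sum(v * EY_i) - sum(w * cs$mu)),
    # within-cross response: v-weighted mean of R_i = H2 (E(Y_i) - mu_i).
    # Unlike S and R above, whose base mean E(X) carries the n_i/N mixture
    # weights, this quantity is invariant under permutation of the mu_i at
    # fixed seg_var/n/s, and E(G) = sum(v_i mu_i) + R_within.
    R_within = H2 * sum(v * (EY_i - cs$mu)),
    EG = sum(v * EG_i)
  )
  structure(list(
    table = data.frame(id = cs$id, mu = cs$mu, seg_var = cs$seg_var,
                       n = n, s = s, w = w, v = v, EY = EY_i, EG = EG_i,
                       stringsAsFactors = FALSE),
    totals = totals,
    scenario = scenario
  ), class = "allocation")
}

#' @export
print.allocation <- function(x, ...) {
  t <- x$totals
  cat("Allocation of N =", x$scenario$N, "individuals to",
      nrow(x$table), "crosses\n")
  cat(sprintf("  E(X) = %.4f  E(Y) = %.4f  S = %.4f  R = %.4f  E(G) = %.4f\n",
              t$EX, t$EY, t$S, t$R, t$EG))
  print.data.frame(x$table, digits = 6, ...)
  invisible(x)
}

#' Expected mean of the base population
#'
#' E(X) = sum of `w_i * mu_i` with mixture weights `w_i = n_i / N`.
#'
#' @inheritParams allocation
#' @param n Family sizes, one per cross.
#' @return Trait-unit expectation.
#' @export
base_expectation <- function(cross_set, n) {
  cs <- as_cross_set(cross_set)
  if (length(n) != nrow(cs))
    ca_stop_validation("'n' must supply one family size per cross")
  sum((n / sum(n)) * cs$mu)
}

#' Expected mean of the total selected fraction
#'
#' E(Y) = sum of `v_i * E(Y_i)` with `v_i = s_i / sum(s)` and E(Y_i) the
#' expected mean of the best `s_i` of `n_i` phenotypes of cross i.
#'
#' @inheritParams allocation
#' @return Trait-unit expectation.
#' @export
selected_fraction_expectation <- function(cross_set, n, scenario) {
  allocation(cross_set, n, scenario)$totals$EY
}

#' Selection differential and response to selection
#'
#' S = E(Y) - E(X); R = H2 * S. `R_within` is the v-weighted mean of the
#' per-cross responses R_i = H2 * (E(Y_i) - mu_i); it is non-negative,
#' feeds E(G), and does not depend on how the cross means are paired with
#' the segregation variances (the base mean of S, by contrast, weights the
#' mu_i by n_i/N).
#'
#' @inheritParams allocation
#' @return Named numeric vector `c(S = , R = , R_within = )`.
#' @export
response_to_selection <- function(cross_set, n, scenario) {
  t <- allocation(cross_set, n, scenario)$totals
  c(S = t$S, R = t$R, R_within = t$R_within)
}

#' Expected genetic value of the next cycle
#'
#' Per cross, E(G_i) = mu_i + H2 * (E(Y_i) - mu_i); the total pools the
#' crosses with their selected-fraction weights `v_i` (the unweighted mean
#' when `s` is constant).
#'
#' @inheritParams allocation
#' @return List with `per_cross` (numeric vector of E(G_i)) and `total`.
#' @export
expected_genetic_value <- function(cross_set, n, scenario) {
  a <- allocation(cross_set, n, scenario)
  list(per_cross = stats::setNames(a$table$EG, a$table$id),
       total = a$totals$EG)
}
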