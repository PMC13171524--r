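# crossalloc

Optimal progeny allocation across crosses via exact normal order
statistics.

Line breeding programs of autogamous crops (barley, wheat) derive inbred —
typically doubled haploid — lines from a fixed set of k crosses. Each cross
i contributes a family of n_i lines whose genotypic values are modeled as
Normal(μ_i, σ*²_i), with cross mean μ_i and segregation variance σ*²_i
predictable from parental marker data. Selection keeps the best s_i
phenotypes per family, observed with heritability H², so the phenotypic
variance is σ²_i = σ*²_i / H². `crossalloc` answers two questions for the
breeder:

1. **Prediction.** What are the expected mean of the selected fraction
   E(Y), the selection differential S = E(Y) − E(X), the response to
   selection R = H²S, and the expected genetic value of the next cycle
   E(G) = (1/k) Σ [μ_i + H²(E(Y_i) − μ_i)], for given family sizes? The
   expectation of the selected fraction of a family is the mean of its s_i
   greatest order statistics,
   E(Y_i) = (1/s_i) Σ_{r=n_i−s_i+1}^{n_i} E(X_(r)), with each
   E(X_(r)) = ∫ x f_(r)(x) dx computed by adaptive quadrature of the
   order-statistic density
   f_(r)(x) = [Γ(n+1)/(Γ(r)Γ(n−r+1))] F(x)^{r−1} (1−F(x))^{n−r} f(x).
   Unlike the classical infinite-population truncation formula
   S = φ(Φ⁻¹(1−α)) σ/α, this is exact for finite family sizes.

2. **Optimization.** How should a fixed total of N individuals be divided
   over the crosses to maximize E(G)? Because each E(G_i) is increasing
   and concave in n_i, a greedy algorithm — start at n_i = s_i, then give
   each remaining individual to the cross with the largest marginal gain —
   attains the global optimum of the integer program Σ n_i = N,
   n_i ≥ s_i. The marginal gain of cross i is H σ*_i Δd(n_i, s_i), where
   d(n, s) is the standardized expected top-fraction mean: the allocation
   depends on the segregation variances only, never on the cross means.

The package ships a 20-cross barley data set (five elite six-row varieties
× four resistance donors) with marker-predicted μ_i and σ*²_i, seeded
generators for synthetic cross sets and non-normal trait samples, the
sensitivity experiments (variance prediction error; skewed / heavy-tailed /
bimodal trait distributions), an exhaustive-search optimality oracle, and a
CLI.

## Worked example

```r
library(crossalloc)

barley <- barley_crosses()           # 20 crosses, yield in dt/ha
scn    <- scenario(N = 400, s = 5, H2 = 0.9)

const <- allocation(barley, rep(20, 20), scn)   # n_i = N/k = 20
opt   <- greedy_allocate(barley, scn)           # optimal n_i

const$totals$EG
#> [1] 91.60282
opt$totals$EG
#> [1] 91.70107
opt$totals$EG - const$totals$EG
#> [1] 0.09825333
head(opt$table[c("id", "mu", "seg_var", "n", "EG")], 4)
#>        id    mu seg_var  n       EG
#> 1 ETIx146 82.85    8.73 22 86.41319
#> 2 ETIxANT 94.23    1.46 12 95.23574
#> 3 ETIxD33 87.10    5.23 18 89.59460
#> 4 ETIxD37 83.53   11.91 25 87.93297
```

Constant family sizes give an expected genetic value of 91.60 dt/ha for
the next cycle; optimizing the family sizes raises it by ~0.10 dt/ha,
moving individuals from low-variance elite × elite crosses (ETI×ANT drops
to 12) to high-variance donor × elite crosses (ETI×D37 rises to 25). Over
the full grid N ∈ {400, 1200} × H² ∈ {0.7, 0.9} × s ∈ {1..5, 10} the gain
ranges from 0.06 to 0.11 dt/ha
(`compare_constant_vs_optimal(barley)`). The optimal family size is
approximately linear in the segregation standard deviation:

```r
reg <- allocation_sigma_regression(
  greedy_allocate(barley, scn, criterion = "continuous"))
predict(reg, c(1.5, 3))
#> [1] 14 22
```

A cross with σ* = 1.5 receives about 14 individuals, a cross with σ* = 3
about 22.

## Command line

```sh
exec/crossalloc optimize --N 400 --s 5 --h2 0.9 --out results/
exec/crossalloc compare-grid --N 400,1200 --s 1,2,3,4,5,10 --h2 0.7,0.9
exec/crossalloc sens-variance --mave 0.05,0.1,0.25 --replicates 100 --seed 1
```

Subcommands: `predict`, `optimize`, `compare-grid`, `sens-variance`,
`sens-normality`, `var-curves`, `simulate-sets`; exit code 0 on success, 2
for validation errors, 3 for numerical errors.

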