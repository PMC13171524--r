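Package: crossalloc
Title: Optimal Progeny Allocation Across Crosses via Normal Order Statistics
Version: 0.1.0
Authors@R:
    person("crossalloc", "developers", email = "crossalloc@example.org",
           role = c("aut", "cre"))
Description: Exact prediction of the response to truncation selection in line
    breeding programs that draw inbred (e.g. doubled haploid) progeny from a
    fixed set of crosses with heterogeneous means and segregation variances.
    Expectations and variances of normal order statistics are computed by
    adaptive quadrature with a gamma-function extension to continuous sample
    sizes, yielding the expected mean of the selected fraction, the selection
    differential, the response to selection and the expected genetic value of
    the next cycle for finite family sizes. A greedy marginal-gain algorithm
    allocates a fixed total number of individuals to the crosses and attains
    the global optimum of the resulting concave integer program; exhaustive
    enumeration, sensitivity experiments for variance prediction error and
    non-normal trait distributions, seeded synthetic data generators and a
    command-line interface are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
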