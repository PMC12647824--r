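Package: saddlerank
Title: Saddlepoint P-Values and Confidence Intervals for Rank Tests on
    Clustered Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Rank-based two-sample and paired tests for clustered data
    (Datta-Satten rank-sum, clustered Wilcoxon signed-rank, and weighted
    logrank tests for right-censored outcomes) with p-values computed from
    the within-cluster permutation distribution.  The permutation mid-p is
    approximated by a double (conditional) saddlepoint approximation of the
    conditional Bernoulli representation of the permutation space, with
    exact-enumeration and Monte Carlo permutation engines as benchmarks,
    an asymptotic normal engine for comparison, test-inversion confidence
    intervals for location and log-time (AFT) shifts, and shared gamma
    frailty simulators for clustered survival and paired data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
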