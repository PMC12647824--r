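# saddlerank

Accurate p-values and confidence intervals for rank-based two-sample and
paired tests on **clustered data**, computed from the within-cluster
permutation distribution via a **double (conditional) saddlepoint
approximation**.

## The problem and who this is for

In multi-centre trials, longitudinal studies and litter-based experiments,
observations within a cluster are correlated, so the usual asymptotic
reference distributions for rank tests can be unreliable, while the exact
within-cluster permutation test is combinatorially expensive.
`saddlerank` is for biostatisticians who want permutation-grade accuracy
at closed-form cost for:

* the **Datta–Satten** cluster-adjusted rank-sum test (`ds`),
* the clustered **Wilcoxon signed-rank** test for paired data (`wsr`),
* weighted **logrank-type** tests for right-censored outcomes —
  logrank (`lr`), Gehan–Wilcoxon (`gw`), Prentice–Wilcoxon (`pw`).

All of these are linear rank statistics
*S* = Σᵢ vᵢ Σⱼ w·ᵢⱼ ζᵢⱼ whose null law is the product of independent
within-cluster permutations of the treatment labels with group sizes
fixed.  That law equals the law of independent Bernoulli(pᵢ) variables
conditioned on their cluster sums, which yields a joint cumulant
generating function

K(t, s) = Σᵢⱼ log(1 − pᵢ + pᵢ exp(t vᵢ wᵢⱼ + sᵢ)),

and the mid-p-value P(S > s_obs) + ½ P(S = s_obs) is approximated by the
Lugannani–Rice-type tail formula
1 − Φ(r̃) + φ(r̃)(1/ũ − 1/r̃) built from the numerator saddlepoint
(t̂, ŝ) of the (M+1)-equation gradient system and the denominator
saddlepoint at t = 0 (exactly **0** when pᵢ = wᵢ/nᵢ).  Exact enumeration
(`exact`), Monte Carlo permutation (`mcp`) and the asymptotic normal
reference (`an`) are provided as companion engines, and confidence
intervals come from test inversion under a location shift (paired) or an
accelerated-failure-time log-time shift (survival).  Shared gamma frailty
simulators reproduce the clustered survival and paired designs used for
validation.

## Worked example

```r
library(saddlerank)

set.seed(6)
dat <- simulate_survival_data(10, sizes = 4, theta = 2.0,
                              baseline = "exponential")   # null data
res <- cluster_rank_test(dat, test = "ds",
                         engine = c("an", "dsa", "mcp"),
                         B = 1e6, seed = 6)
print(res)
#> Clustered rank test: DS ( 10 clusters )
#>   S_obs = -6.5 | perm mean = 0 | perm sd = 3.1108
#>   mid-p [an, two.sided] = 0.0366633
#>   mid-p [dsa, two.sided] = 0.0333808
#>   mid-p [mcp, two.sided] = 0.033493
```

The saddlepoint value (0.03338) matches the B = 10⁶ permutation benchmark
(0.03349) to about 1e-4 at a tiny fraction of its cost, while the normal
approximation is visibly off (0.03666).  A confidence interval for a
paired treatment effect, on the packaged synthetic fixture shaped like a
large paired trial (294 clusters, 1–8 subunits each, true shift 0.5):

```r
pair <- read_clustered_data(system.file("extdata",
          "synthetic_toenail_shape.csv", package = "saddlerank"), "paired")
invert_test(pair, test = "wsr", engine = "dsa", level = 0.95,
            effect_model = "location_shift")
#> 95% CI by WSR-test inversion (dsa engine): 0.6235 [0.4712, 0.6974]
```

The same analyses run from a shell through the thin wrapper in
`inst/scripts/`:

```sh
clusrank-saddle test --input data.csv --test lr --engine dsa,mcp \
                     --B 100000 --seed 7 --out result.json
clusrank-saddle ci   --input pairs.csv --test wsr --engine dsa --level 0.95
clusrank-saddle simulate --test ds --M 10 --theta 0.5 --reps 2000 --out grid.tsv
```

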