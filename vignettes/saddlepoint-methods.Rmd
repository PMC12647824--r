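---
title: "Saddlepoint inference for clustered rank tests: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saddlepoint inference for clustered rank tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saddlerank)
```

## The inferential problem

Clustered designs — patients contributing repeated events, litters,
clinics — violate the independence assumption behind the usual rank tests.
`saddlerank` works with the *within-cluster permutation* reference
distribution: treatment labels are exchangeable only among subjects of the
same cluster, with the per-cluster group sizes $w_i$ held fixed.  All five
supported tests are linear rank statistics
$$S=\sum_{i=1}^{M} v_i \sum_{j=1}^{n_i} w_{ij}\,\zeta_{ij},$$
where the scores $w_{ij}$ are computed once from the observed outcomes and
then treated as fixed constants:

* **ds** — Datta–Satten cluster-adjusted rank-sum scores
  $w_{ij}=1+\tfrac12\sum_{k\neq i}\{F_k(y_{ij})+F_k(y_{ij}^-)\}$, built
  from the other clusters' empirical distribution functions (ties handled
  through the left limit; censored observations enter through the observed
  time, which is flagged in the documentation).
* **wsr** — clustered Wilcoxon signed-rank: pooled mid-ranks of $|D_{ij}|$
  with $\zeta_{ij}=I(D_{ij}>0)$; the permutation law conditions on the
  per-cluster count of positive differences.
* **lr / gw / pw** — weighted logrank scores for right-censored data:
  observed-minus-expected event contributions over the pooled risk sets
  with time weight $1$, $Y(t)/N$, or the left-continuous Kaplan–Meier
  estimate.  The two-sample integrand weights of the classical
  presentations carry a variance-normalising factor
  $Y_1Y_2/(Y_1+Y_2)$; that factor is part of the standardisation, not of
  the per-subject score, and is absorbed here by the permutation moments.
  The construction is validated against exact enumeration rather than any
  closed form.

Two cluster-weight rules are provided: $v_i = 1$ (default) and the
Wilcoxon-type $v_i = 1/(n_i+1)$.  Scores are centred within clusters by
default so the permutation mean of $S$ is exactly zero; the variance
$$\operatorname{Var}(S)=\sum_i v_i^2
  \frac{w_i(n_i-w_i)}{n_i(n_i-1)}\sum_j (w_{ij}-\bar w_{i\cdot})^2$$
is then the *exact* second moment of the permutation law (verified against
full enumeration in the tests).

## The double saddlepoint approximation

The permutation law of the labels equals the law of independent
Bernoulli$(p_i)$ variables conditioned on their cluster sums, which gives
the joint CGF
$$K(t,\mathbf s)=\sum_{i,j}\log\!\left(1-p_i+p_i e^{t v_i w_{ij}+s_i}\right).$$
The nuisance probabilities do not affect the conditional law; fixing
$p_i=w_i/n_i$ makes the denominator (constraint-only) saddlepoint exactly
$\mathbf{\hat s}_0=\mathbf 0$.  The numerator saddlepoint solves
$\nabla K(\hat t,\hat{\mathbf s})=(s_{\mathrm{obs}},w_1,\dots,w_M)$; the
mid-p-value $P(S>s_{\mathrm{obs}})+\tfrac12 P(S=s_{\mathrm{obs}})$ is then
approximated by the Lugannani–Rice-type tail formula
$$1-\Phi(\tilde r)+\phi(\tilde r)\left(\frac1{\tilde u}-\frac1{\tilde r}\right),$$
with $\tilde r$ the signed root of twice the Legendre-transform difference
and $\tilde u=\hat t\,(\det K''/\det K''_{ss})^{1/2}$.  The orientation of
the correction term follows the classical tail formula; it is the only
orientation that reproduces known benchmarks (a Gamma tail, exact
permutation enumerations) and the discrete lower/upper complementarity.

### Numerical design

* **Nested profiling instead of a full Newton.**  For fixed $t$ each
  cluster tilt solves a strictly increasing one-dimensional equation; a
  bracketed, vectorised Newton–bisection solves all clusters at once (the
  equations become near-staircases at large $|t|$, where an unguarded
  Newton oscillates).  The profiled outer equation in $t$ is strictly
  increasing and solved by safeguarded Newton with bisection fallback.
  Solutions are identical to the $(M{+}1)$-dimensional system at $O(M)$
  cost per iteration.  Residual tolerance $10^{-8}$ (relative to
  $\max(1,|s_{\mathrm{obs}}|)$), up to 200 outer iterations to let the
  bisection tail finish near support edges; convergence metadata are
  returned in the solution object.
* **Determinants via the arrow structure.**  $K''$ is diagonal in the
  $s$-block, so $\det K''=(\prod_i K''_{ss,ii})\cdot(K''_{tt}-\sum_i
  K''^2_{ts,i}/K''_{ss,ii})$, accumulated in log space; the full matrix is
  never formed.  A dense-determinant oracle cross-checks this at small
  $M$ in the tests.
* **Stability.**  Bernoulli means are evaluated as
  `plogis(eta + qlogis(p))` and log terms in a two-branch stable form, so
  tilts with $|\eta|$ up to several hundred cause no overflow.
* **Small tilts.**  $1/\tilde u - 1/\tilde r$ is numerically catastrophic
  near $\hat t = 0$; for $|\hat t|<10^{-5}$ it is replaced by its analytic
  limit $-\lambda_3/6$, the standardised third cumulant of the profiled
  conditional CGF at the origin (obtained by finite differences of the
  profiled mean function), so the value tends to $1/2$ plus a skewness
  correction.
* **Boundary atoms.**  When $s_{\mathrm{obs}}$ sits at the support
  maximum the upper mid-p is $\tfrac12 P(S=\max)$, taken from exact
  enumeration when the assignment space is below `max_space`
  ($2\times10^6$) and otherwise reported as 0 with a warning.
* **Inactive clusters.**  Clusters with $w_i\in\{0,n_i\}$ or constant
  scores contribute a known constant to $S$ and are removed from the
  active system (their offset is subtracted from the target).
* **Sidedness.**  The lower tail re-runs the machinery on negated tilt
  coefficients; `two.sided` is $\min(1,\,2\min(p_\mathrm{up},
  p_\mathrm{low}))$.  Sidedness conventions vary across the clustered
  rank-test literature; this min-doubling rule is used everywhere in the
  package and kept behind a single argument.

### Accuracy, honestly stated

The tail formula is a smooth approximation evaluated at an atom of a
discrete distribution.  Its error therefore scales with the coarseness of
the attainable support.  Measured against exact enumeration:

* With $M\geq 10$ clusters of realistic size (the regime the method is
  designed for), the upper mid-p agrees with a $B=10^5$ permutation
  benchmark to a median of about $2\times10^{-3}$, with ~99% of datasets
  within 0.01.
* On deliberately tiny instances ($M\in\{2,\dots,5\}$, $n_i\leq 5$, as
  few as 4–30 attainable atoms) the median error is around
  $5\times10^{-3}$ and worst cases reach several hundredths: the exact
  mid-p jumps by $O(1/\#\text{atoms})$ between neighbouring atoms, which
  no continuous formula can track.  A Skovgaard-type lattice continuity
  correction (offset saddle with $\sinh$-modified $\tilde u$) was
  evaluated and did not improve on the direct formula, besides being
  undefined for the non-lattice survival scores; the package therefore
  keeps the direct mid-p formula everywhere and ships the exact
  enumeration engine for small problems.

## Permutation engines

`exact_midp` enumerates the product of per-cluster assignment spaces
(capped at $2\times10^6$ states) and is the ground-truth oracle.
`mcp_midp` implements the benchmark estimator
$B^{-1}\{\sum_b I(S_b>S_{\mathrm{obs}})+\tfrac12\sum_b
I(S_b=S_{\mathrm{obs}})\}$ with statistic-equality tolerance $10^{-9}$
(scores are small-denominator rationals after mid-ranking, so genuinely
distinct atoms are separated by far more).  `an_midp` is the normal
reference using the exact permutation moments — no continuity correction.

## Confidence intervals by test inversion

The $(1-\alpha)$ interval collects the effects $\beta_0$ whose
shifted-data two-sided mid-p stays at or above $\alpha$.  For paired data
the shift is the location model $d\mapsto d-\beta_0$.  For survival tests
the adjustment is the accelerated-failure-time log-time shift (treated
times multiplied by $e^{-\beta_0}$, censoring times shifted identically so
event indicators are untouched).  Two design points deserve emphasis:

* **Orientation.**  The simulator's truth is a proportional-hazards
  log-hazard ratio $\beta$ (treated times *shorter* when $\beta>0$), so
  the package inverts over the *negative* AFT shift, which coincides with
  the log-hazard ratio exactly under an exponential baseline and keeps
  estimates sign-compatible with frailty-model output.  Under a Weibull
  baseline with shape $\alpha$ the AFT estimand is $\beta/\alpha$; this
  PH/AFT mismatch is intrinsic to pairing a hazard-model simulator with a
  time-shift inversion and shows up as slight undercoverage in the
  Weibull CI scenarios.
* **Degenerate shifts.**  A location shift beyond the data range flips
  every difference to one sign; the strictly conditional test then
  carries no information.  The inversion search treats such $\beta_0$ as
  decisively rejected so the bisection brackets stay well defined.  When a
  very discrete configuration's p-value never crosses $\alpha$ on one
  side, that endpoint is reported as unbracketable (the interval is
  effectively unbounded there).

Endpoints are located by bisection on $p(\beta_0)-\alpha$ to
$|p-\alpha|\le10^{-3}$ or a $\beta$-resolution of $10^{-4}$, from brackets
expanded geometrically off a curvature-based standard-error estimate
(at most 8 doublings).  The Monte Carlo engine reuses one seed across all
$\beta_0$ evaluations (common random numbers) so its p-curve is
effectively monotone along each search arm.  The point estimate is the
Hodges–Lehmann-style zero crossing of the standardised statistic.  A Wald
interval from a shared gamma frailty fit (via the survival package) is
available as `frailty_an_ci()` purely as a comparator; the package's own
intervals are always inversion intervals.

## The synthetic-data generators

`simulate_survival_data` implements a shared gamma frailty model: one
$u_i\sim\Gamma(\text{mean }1,\text{var }\theta)$ per cluster,
conditional hazard $u_i\,h_0(t)\,e^{\beta\zeta}$, inverse-transform event
times $T=\{-\log V/(u\lambda e^{\beta\zeta})\}^{1/\alpha}$ with
$H_0(t)=\lambda t^\alpha$ (exponential $\lambda=0.1$;
Weibull $\alpha=1.5$, $\lambda=0.05$ — the power-form parameterisation is
a package choice isolated in one function; it affects the time scale
only, not null rank-test behaviour).  Administrative censoring truncates
at a fixed $C$; `calibrate_censoring` returns the $C$ matching a target
censoring fraction as the corresponding quantile of a large simulated
pool of event times ($10^5$ subjects), equivalent to root-finding on
$P(T>C)$.  Treated counts are $w_i=\lfloor n_i/2\rfloor$, assigned by a
random within-cluster permutation (a package choice: the balanced split
guarantees non-degenerate clusters), so
cluster sizes must be at least 2.  Null scenario grids apply no censoring
unless asked (a stated fraction appears only in the CI study design).

`simulate_paired_data` follows the stated hierarchy exactly:
$Z_{ij}\sim N(u_i,\sigma_Z^2)$ (default $\sigma_Z=1$, a package choice),
$Y_1=Z+\varepsilon_1$, $Y_2=Z+\beta+\varepsilon_2$ with independent
$N(0,1)$ errors.  Note the consequence: the differences
$D=\beta+\varepsilon_2-\varepsilon_1$ are then independent of $u_i$ and
carry *no* intra-cluster correlation — so a normal-theory WSR test is not
expected to misbehave under this model no matter the $\theta$.  An
optional `cluster_shift_sd` adds a shared per-cluster component to the
differences for users who want genuinely correlated paired data; it is
off by default because the stated model is implemented as written.

What passing tests on these generators show — and what they do not: the
generators emulate frailty-type correlation with balanced within-cluster
randomisation, continuous outcomes, and administrative censoring.  They do
not emulate informative censoring, covariate-dependent frailties,
unbalanced/confounded treatment assignment, or heavily tied outcome
scales; conclusions about those settings do not follow from these tests.

## Problem sizes used in the shipped checks

The packaged test-suite scenarios use $M=10$ clusters of size 4 at 2,000
null replicates for rejection rates, 500 replicates for CI coverage
(Weibull, 20% censoring, $\beta=\log 1.5$) and paired-effect recovery
($M=30$, $\beta=0.5$), 300 datasets for the $B=10^5$ benchmark-agreement
check, and 200 random small instances against exact enumeration — sizes
chosen so each check carries useful Monte Carlo resolution (binomial SE
$\approx0.005$–$0.015$) while the whole suite stays convenient to run.
The acceptance script re-runs the $M=50$, $\theta=2$ null grid at 10,000
replicates.

## Known limitations

* Two arms only; no stratification, interval censoring, or covariate
  adjustment.
* The saddlepoint error on very coarse lattices (a handful of clusters of
  size 2–3) is bounded in practice by a few hundredths — use the exact
  engine there; it is cheap precisely in that regime.
* The third-order (Skovgaard $\rho_3$/$\rho_4$) refinement is not
  implemented.
* CI inversion under the Weibull simulator inherits the PH-vs-AFT
  estimand mismatch described above.
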