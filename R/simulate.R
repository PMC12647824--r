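#' Draw shared cluster frailties
#'
#' Gamma frailties with mean 1 and variance theta (shape 1/theta, scale
#' theta); theta = 0 returns exactly 1 (no heterogeneity).
#'
#' @param n number of draws.
#' @param theta frailty variance, >= 0.
#' @return numeric vector of positive frailties.
#' @export
draw_frailty <- function(n, theta) {
  if (theta < 0) stop("theta must be >= 0")
  if (theta == 0) return(rep(1, n))
  stats::rgamma(n, shape = 1 / theta, scale = theta)
}

# internal: resolve the cluster-size rule.  A single integer means fixed
# sizes; a length-2 vector means discrete uniform on [a, b]; a length-M
# vector is used as-is.
resolve_sizes <- function(sizes, M) {
  if (length(sizes) == 1L) return(rep(as.integer(sizes), M))
  if (length(sizes) == 2L)
    return(sample(seq.int(sizes[1L], sizes[2L]), M, replace = TRUE))
  if (length(sizes) == M) return(as.integer(sizes))
  stop("sizes must have length 1 (fixed), 2 (uniform range) or M")
}

#' Simulate clustered survival data from a shared gamma frailty model
#'
#' Each cluster draws one frailty u_i (gamma, mean 1, variance theta); each
#' subject's event time follows the conditional hazard
#' u_i h0(t) exp(beta zeta) via inverse-transform sampling,
#' T = H0^{-1}(-log V / (u_i e^{beta zeta})), with cumulative baseline
#' hazard H0(t) = lambda t^alpha (alpha = 1 gives the exponential
#' baseline).  Treated counts are w_i = floor(n_i / 2), assigned by a
#' random within-cluster permutation, so every cluster holds both arms
#' (cluster sizes must be >= 2).  Administrative censoring at time C gives
#' observed y = min(T, C) and event = I(T <= C).
#'
#' @param M number of clusters.
#' @param sizes cluster-size rule (see Details of [resolve_sizes]):
#'   default 4 (balanced); `c(2, 8)` draws sizes uniformly on 2..8.
#' @param theta frailty variance.
#' @param baseline "exponential" (lambda = 0.1) or "weibull"
#'   (alpha = 1.5, lambda = 0.05); lambda/alpha may be overridden.
#' @param lambda,alpha baseline hazard parameters (H0(t) = lambda t^alpha).
#' @param beta log-hazard ratio of the treated arm (0 under the null).
#' @param censor_time administrative censoring time C (Inf = none).
#' @return clustered survival data.frame (cluster, y, event, arm).
#' @export
simulate_survival_data <- function(M, sizes = 4, theta = 0,
                                   baseline = c("exponential", "weibull"),
                                   lambda = NULL, alpha = NULL,
                                   beta = 0, censor_time = Inf) {
  baseline <- match.arg(baseline)
  if (is.null(lambda)) lambda <- switch(baseline, exponential = 0.1,
                                        weibull = 0.05)
  if (is.null(alpha)) alpha <- switch(baseline, exponential = 1,
                                      weibull = 1.5)
  stopifnot(M >= 1, lambda > 0, alpha > 0)
  n_i <- resolve_sizes(sizes, M)
  if (any(n_i < 2))
    stop("two-sample clusters need n_i >= 2 to hold both arms")
  u <- draw_frailty(M, theta)
  cl <- rep(seq_len(M), n_i)
  w_i <- n_i %/% 2L
  arm <- unlist(lapply(seq_len(M), function(i)
    sample(rep(c(1L, 0L), c(w_i[i], n_i[i] - w_i[i])))), use.names = FALSE)
  V <- stats::runif(length(cl))
  rate <- u[cl] * exp(beta * arm)
  T <- (-log(V) / (rate * lambda))^(1 / alpha)
  data.frame(cluster = cl, y = pmin(T, censor_time),
             event = as.integer(T <= censor_time), arm = arm)
}

#' Calibrate the administrative censoring time to a target fraction
#'
#' Simulates a large pool of uncensored event times under the scenario and
#' returns the (1 - target) empirical quantile, i.e. the time C at which
#' P(T > C) equals the target censoring fraction to Monte Carlo accuracy.
#'
#' @param target target censoring fraction in (0, 1).
#' @param M,sizes,theta,baseline,lambda,alpha,beta scenario parameters
#'   passed to [simulate_survival_data()].
#' @param n_subjects approximate pool size for the calibration.
#' @return censoring time C.
#' @export
calibrate_censoring <- function(target, M = 50, sizes = 4, theta = 0,
                                baseline = c("exponential", "weibull"),
                                lambda = NULL, alpha = NULL, beta = 0,
                                n_subjects = 1e5) {
  stopifnot(target > 0, target < 1)
  baseline <- match.arg(baseline)
  avg_n <- mean(resolve_sizes(sizes, max(M, 50)))
  n_clusters <- ceiling(n_subjects / avg_n)
  pool <- simulate_survival_data(n_clusters, sizes = sizes, theta = theta,
                                 baseline = baseline, lambda = lambda,
                                 alpha = alpha, beta = beta,
                                 censor_time = Inf)
  unname(stats::quantile(pool$y, probs = 1 - target, type = 7))
}

#' Simulate clustered paired data
#'
#' Hierarchy: cluster effect u_i ~ gamma(mean 1, variance theta); latent
#' subunit effect Z_ij ~ N(u_i, sigma_z^2); paired outcomes
#' Y1 = Z + e1 and Y2 = Z + beta + e2 with independent N(0, 1) errors.
#' The returned differences D = Y2 - Y1 = beta + e2 - e1 are, as written,
#' independent of the cluster effects; the optional
#' `cluster_shift_sd > 0` adds a shared N(0, sd^2) cluster-level component
#' to every difference in a cluster, an exploratory mode for inducing
#' intra-cluster correlation of the differences.
#'
#' @param M number of clusters.
#' @param sizes cluster-size rule (single value, range, or length-M).
#' @param theta cluster-effect variance.
#' @param beta true treatment effect on the second measurement.
#' @param sigma_z sd of the latent subunit effect (default 1).
#' @param cluster_shift_sd optional sd of a shared per-cluster difference
#'   component (default 0 = the model exactly as specified).
#' @return paired data.frame (cluster, subunit, y1, y2, d).
#' @export
simulate_paired_data <- function(M, sizes = 4, theta = 0, beta = 0,
                                 sigma_z = 1, cluster_shift_sd = 0) {
  stopifnot(M >= 1, sigma_z >= 0, cluster_shift_sd >= 0)
  n_i <- resolve_sizes(sizes, M)
  u <- draw_frailty(M, theta)
  cl <- rep(seq_len(M), n_i)
  Z <- stats::rnorm(length(cl), mean = u[cl], sd = sigma_z)
  y1 <- Z + stats::rnorm(length(cl))
  y2 <- Z + beta + stats::rnorm(length(cl))
  if (cluster_shift_sd > 0) {
    delta <- stats::rnorm(M, sd = cluster_shift_sd)
    y2 <- y2 + delta[cl]
  }
  data.frame(cluster = cl,
             subunit = stats::ave(cl, cl, FUN = seq_along),
             y1 = y1, y2 = y2, d = y2 - y1)
}

#' Run a simulation scenario grid
#'
#' For every scenario row and requested engine this computes, over `reps`
#' replicates, the empirical rejection rate of the two-sided mid-p test at
#' `alpha` (null mode, beta = 0) or the coverage and mean length of the
#' level-`level` inversion CI (effect mode), with binomial Monte Carlo
#' standard errors.  Scenario columns: `M`, `size_rule` ("fixed4" or
#' "unif2_8"), `theta`, `baseline` ("exponential"/"weibull"), `beta`,
#' `censor_frac` (0 = none), and for the WSR test `sigma_z`.  Results are
#' deterministic given `seed` (per-replicate child seeds are drawn up
#' front).
#'
#' @param scenarios data.frame of scenario rows.
#' @param test test name.
#' @param engines character vector of p-value engines.
#' @param reps replicates per scenario.
#' @param mode "type1" or "ci".
#' @param alpha nominal level for rejection (type1 mode).
#' @param level CI level (ci mode).
#' @param B Monte Carlo permutations for the "mcp" engine.
#' @param seed master seed.
#' @return long-format data.frame of results.
#' @export
run_scenario_grid <- function(scenarios, test = "ds",
                              engines = c("an", "dsa"),
                              reps = 200, mode = c("type1", "ci"),
                              alpha = 0.05, level = 0.95, B = 1e4,
                              seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  out <- list()
  for (sidx in seq_len(nrow(scenarios))) {
    sc <- scenarios[sidx, ]
    sizes <- switch(as.character(sc$size_rule),
                    fixed4 = 4, unif2_8 = c(2, 8),
                    as.numeric(sc$size_rule))
    beta <- if (is.null(sc$beta)) 0 else sc$beta
    cf <- if (is.null(sc$censor_frac)) 0 else sc$censor_frac
    child <- sample.int(.Machine$integer.max, reps)
    C <- Inf
    if (test != "wsr" && cf > 0)
      C <- calibrate_censoring(cf, theta = sc$theta, sizes = sizes,
                               baseline = as.character(sc$baseline),
                               beta = beta)
    stat <- matrix(NA_real_, reps, length(engines),
                   dimnames = list(NULL, engines))
    len <- stat
    for (r in seq_len(reps)) {
      set.seed(child[r])
      if (test == "wsr") {
        dat <- simulate_paired_data(sc$M, sizes = sizes, theta = sc$theta,
                                    beta = beta,
                                    sigma_z = if (is.null(sc$sigma_z)) 1
                                              else sc$sigma_z)
      } else {
        dat <- simulate_survival_data(sc$M, sizes = sizes,
                                      theta = sc$theta,
                                      baseline = as.character(sc$baseline),
                                      beta = beta, censor_time = C)
      }
      for (e in engines) {
        if (mode == "type1") {
          scs <- clustered_scores(dat, test = test)
          p <- switch(e,
            an = an_midp(scs, "two.sided"),
            dsa = as.numeric(dsa_midp(scs, "two.sided")),
            mcp = as.numeric(mcp_midp(scs, B = B, side = "two.sided")),
            exact = as.numeric(exact_midp(scs, "two.sided")))
          stat[r, e] <- as.numeric(p < alpha)
        } else {
          em <- if (test == "wsr") "location_shift" else "log_time_shift"
          ci <- tryCatch(
            invert_test(dat, test = test, engine = e, level = level,
                        effect_model = em, B = B, seed = child[r]),
            error = function(er) {
              # an endpoint whose discrete p never crosses alpha leaves
              # that side unbounded: counted as covering
              if (grepl("unbracketable", conditionMessage(er))) NULL
              else stop(er)
            })
          stat[r, e] <- if (is.null(ci)) 1 else
            as.numeric(ci$lower <= beta && beta <= ci$upper)
          len[r, e] <- if (is.null(ci)) NA_real_ else ci$upper - ci$lower
        }
      }
    }
    for (e in engines) {
      rate <- mean(stat[, e])
      out[[length(out) + 1L]] <- data.frame(
        scenario = sidx, M = sc$M, size_rule = sc$size_rule,
        theta = sc$theta,
        baseline = if (is.null(sc$baseline)) NA else
          as.character(sc$baseline),
        beta = beta, test = test, engine = e, reps = reps,
        metric = if (mode == "type1") "rejection_rate" else "coverage",
        value = rate,
        mc_se = sqrt(rate * (1 - rate) / reps),
        mean_ci_length = if (mode == "ci") mean(len[, e], na.rm = TRUE)
                         else NA_real_,
        seed = seed)
    }
  }
  do.call(rbind, out)
}
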