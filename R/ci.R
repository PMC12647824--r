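#' Shift data to conform to a hypothesized treatment effect
#'
#' Test inversion requires, for each hypothesized effect beta0, a dataset
#' that satisfies the null once the effect is removed.  Under the
#' accelerated-failure-time model (`log_time_shift`) beta0 is subtracted
#' from the log times of the treated arm, i.e. treated times become
#' y * exp(-beta0); censoring times are shifted together with event times,
#' so event indicators are unchanged.  Under `location_shift` (paired
#' data) beta0 is subtracted from every paired difference.
#'
#' @param data two-sample survival data or paired data.
#' @param beta0 hypothesized effect.
#' @param effect_model "log_time_shift" or "location_shift".
#' @return adjusted data.frame.
#' @export
shift_adjust <- function(data, beta0,
                         effect_model = c("log_time_shift",
                                          "location_shift")) {
  effect_model <- match.arg(effect_model)
  if (effect_model == "log_time_shift") {
    data <- as_clustered_data(data)
    if (any(data$y <= 0))
      stop("log_time_shift requires strictly positive times")
    data$y[data$arm == 1] <- data$y[data$arm == 1] * exp(-beta0)
  } else {
    data <- as_paired_data(data)
    data$d <- data$d - beta0
  }
  data
}

# internal: orientation of the inversion parameter.  For paired data the
# effect is the location shift itself.  For survival tests the reported
# effect is oriented like the log-hazard ratio (positive = earlier events
# in the treated arm), which is the NEGATIVE of the AFT log-time shift that
# shift_adjust() applies; under an exponential baseline the two
# parameterizations coincide exactly.
effect_adjust <- function(data, b, effect_model) {
  sgn <- if (effect_model == "log_time_shift") -1 else 1
  shift_adjust(data, sgn * b, effect_model)
}

# internal: side information for degenerate shifted configurations.  For a
# location shift a beta0 beyond the data range flips every difference to
# one sign; the within-cluster permutation distribution then degenerates
# (every w_i is 0 or n_i) and the strictly conditional test carries no
# information.  For the inversion search such a beta0 is treated as
# decisively rejected (p = 0) with the direction recorded, so brackets and
# bisection remain well defined.  beta0 values that reproduce the data
# exactly (all differences zero) count as perfect agreement instead.
degenerate_side <- function(adj, effect_model) {
  if (effect_model == "location_shift") {
    sgn <- sign(adj$d)
    if (all(sgn == 0)) return(0)
    if (all(sgn <= 0)) return(-1)
    if (all(sgn >= 0)) return(1)
  }
  0
}

# internal: two-sided mid-p at a hypothesized effect
shifted_pvalue <- function(data, beta0, test, engine, effect_model,
                           B, seed, v_rule, center, max_space) {
  adj <- effect_adjust(data, beta0, effect_model)
  tryCatch({
    sc <- clustered_scores(adj, test = test, v_rule = v_rule,
                           center = center)
    if (permutation_moments(sc)$var <= 0)
      return(if (degenerate_side(adj, effect_model) == 0) 1 else 0)
    switch(engine,
      an = an_midp(sc, "two.sided"),
      dsa = as.numeric(dsa_midp(sc, "two.sided", max_space = max_space)),
      exact = as.numeric(exact_midp(sc, "two.sided",
                                    max_space = max_space)),
      mcp = {
        if (!is.null(seed)) set.seed(seed)  # common random numbers
        as.numeric(mcp_midp(sc, B = B, side = "two.sided"))
      })
  }, error = function(e) {
    if (!grepl("degenerate", conditionMessage(e))) stop(e)
    if (degenerate_side(adj, effect_model) == 0) 1 else 0
  })
}

# internal: standardized statistic at a hypothesized effect (0 when the
# shifted data reproduce the null exactly; +/- large when the shift has
# pushed every paired difference to one sign)
shifted_zstat <- function(data, beta0, test, effect_model, v_rule, center) {
  adj <- effect_adjust(data, beta0, effect_model)
  tryCatch({
    sc <- clustered_scores(adj, test = test, v_rule = v_rule,
                           center = center)
    mom <- permutation_moments(sc)
    if (mom$var <= 0) return(1e6 * degenerate_side(adj, effect_model))
    (observed_statistic(sc) - mom$mean) / sqrt(mom$var)
  }, error = function(e) {
    if (!grepl("degenerate", conditionMessage(e))) stop(e)
    1e6 * degenerate_side(adj, effect_model)
  })
}

#' Point estimate of the treatment effect by statistic inversion
#'
#' The Hodges-Lehmann-style estimate: the beta0 at which the standardized
#' statistic (S(beta0) - mean)/sd crosses zero, located by bisection with
#' geometric bracket expansion.  For paired data the effect is the location
#' shift of the differences; for survival tests it is oriented like the
#' log-hazard ratio (positive = earlier events in the treated arm), the
#' negative of the AFT log-time shift applied by [shift_adjust()].
#'
#' @param data input data.
#' @param test test name.
#' @param effect_model "log_time_shift" or "location_shift".
#' @param v_rule,center score options.
#' @param resolution bisection stops at this beta resolution.
#' @return numeric estimate.
#' @export
point_estimate <- function(data, test = c("ds", "lr", "gw", "pw", "wsr"),
                           effect_model = c("log_time_shift",
                                            "location_shift"),
                           v_rule = c("unit", "wilcoxon_type"),
                           center = TRUE, resolution = 1e-4) {
  test <- match.arg(test)
  effect_model <- match.arg(effect_model)
  v_rule <- match.arg(v_rule)
  zfun <- function(b) shifted_zstat(data, b, test, effect_model, v_rule,
                                    center)
  z0 <- zfun(0)
  if (z0 == 0) return(0)
  # bracket the zero crossing, probing both directions (the statistic is a
  # step function of beta0, so a local slope probe is not reliable)
  lo <- hi <- NULL
  for (k in 1:60) {
    for (cand in c(2^(k - 1), -2^(k - 1))) {
      zc <- zfun(cand)
      if (zc == 0 || sign(zc) != sign(z0)) {
        lo <- min(0, cand); hi <- max(0, cand)
        break
      }
    }
    if (!is.null(lo)) break
  }
  if (is.null(lo)) stop("point estimate: failed to bracket zero crossing")
  # bisection on the sign of z
  zlo <- zfun(lo)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if ((hi - lo) < resolution) break
    zm <- zfun(mid)
    if (zm == 0) { lo <- hi <- mid; break }
    if (sign(zm) == sign(zlo)) { lo <- mid; zlo <- zm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Confidence interval for the treatment effect by test inversion
#'
#' The (1-alpha) interval is the set of hypothesized effects beta0 whose
#' shifted-data two-sided mid-p is at least alpha (effect orientation as in
#' [point_estimate()]).  Each endpoint is found
#' by bisection on p(beta0) - alpha between the point estimate (where p is
#' near 1) and an outer bracket expanded geometrically from the normal-
#' theory interval estimate +/- 4 SE.  For the Monte Carlo engine the same
#' seed is reused at every beta0 (common random numbers), keeping p
#' effectively monotone along each arm of the search.
#'
#' @param data input data.
#' @param test test name.
#' @param engine "an", "dsa", "mcp" or "exact".
#' @param level confidence level (default 0.95).
#' @param effect_model "log_time_shift" or "location_shift".
#' @param B permutations per evaluation for the "mcp" engine (>= 1e4).
#' @param seed seed used for every "mcp" evaluation.
#' @param v_rule,center score options.
#' @param p_tol,resolution endpoint stopping rules: |p - alpha| <= p_tol or
#'   beta-resolution reached.
#' @param max_expand bracket expansion attempts before giving up.
#' @param max_space enumeration cap for the "exact" engine.
#' @return object of class `saddlerank_ci` with estimate, lower, upper,
#'   level and the inversion trace.
#' @export
invert_test <- function(data, test = c("ds", "lr", "gw", "pw", "wsr"),
                        engine = c("dsa", "an", "mcp", "exact"),
                        level = 0.95,
                        effect_model = c("log_time_shift", "location_shift"),
                        B = 1e4, seed = 1L,
                        v_rule = c("unit", "wilcoxon_type"), center = TRUE,
                        p_tol = 1e-3, resolution = 1e-4,
                        max_expand = 8L, max_space = 2e6) {
  test <- match.arg(test)
  engine <- match.arg(engine)
  effect_model <- match.arg(effect_model)
  v_rule <- match.arg(v_rule)
  if (engine == "mcp" && B < 1e4) B <- 1e4
  alpha <- 1 - level
  trace <- new.env()
  trace$beta0 <- numeric(0)
  trace$p <- numeric(0)
  pfun <- function(b) {
    p <- shifted_pvalue(data, b, test, engine, effect_model, B, seed,
                        v_rule, center, max_space)
    trace$beta0 <- c(trace$beta0, b)
    trace$p <- c(trace$p, p)
    p
  }
  est <- point_estimate(data, test, effect_model, v_rule, center,
                        resolution)
  # crude curvature-based SE of the estimate for the initial bracket width
  delta <- max(abs(est) * 0.1, 0.1)
  z1 <- shifted_zstat(data, est + delta, test, effect_model, v_rule, center)
  z2 <- shifted_zstat(data, est - delta, test, effect_model, v_rule, center)
  slope <- abs(z1 - z2) / (2 * delta)
  se <- if (slope > 0) 1 / slope else delta
  endpoint <- function(dirn) {
    inner <- est
    p_inner <- pfun(inner)
    if (p_inner < alpha)
      stop("p-value below alpha at the point estimate; ",
           "cannot invert the test")
    width <- 4 * se
    outer <- NULL
    for (k in seq_len(max_expand)) {
      cand <- est + dirn * width
      if (pfun(cand) < alpha) { outer <- cand; break }
      width <- width * 2
    }
    if (is.null(outer))
      stop("unbracketable endpoint: p(beta0) stayed above alpha after ",
           max_expand, " expansions (flat p-value)")
    repeat {
      mid <- (inner + outer) / 2
      pm <- pfun(mid)
      if (abs(pm - alpha) <= p_tol || abs(outer - inner) < resolution)
        return(mid)
      if (pm >= alpha) inner <- mid else outer <- mid
    }
  }
  lower <- endpoint(-1)
  upper <- endpoint(+1)
  ord <- order(trace$beta0)
  structure(list(estimate = est, lower = lower, upper = upper,
                 level = level, test = test, engine = engine,
                 effect_model = effect_model,
                 trace = data.frame(beta0 = trace$beta0[ord],
                                    p = trace$p[ord])),
            class = "saddlerank_ci")
}

#' @export
print.saddlerank_ci <- function(x, ...) {
  cat(sprintf("%g%% CI by %s-test inversion (%s engine): %.4f [%.4f, %.4f]\n",
              100 * x$level, toupper(x$test), x$engine,
              x$estimate, x$lower, x$upper))
  invisible(x)
}

#' Frailty-model Wald confidence interval (adapter)
#'
#' Optional comparator: fits a shared gamma frailty proportional-hazards
#' model with \pkg{survival} and returns the Wald interval
#' beta_hat +/- z SE for the log-hazard ratio.  This is ordinary
#' off-the-shelf estimation, provided for side-by-side comparison tables;
#' the package's own intervals come from [invert_test()].
#'
#' @param data clustered survival data.
#' @param level confidence level.
#' @return list with estimate, se, lower, upper.
#' @export
frailty_an_ci <- function(data, level = 0.95) {
  if (!requireNamespace("survival", quietly = TRUE))
    stop("the survival package is required for frailty_an_ci()")
  data <- as_clustered_data(data)
  fit <- survival::coxph(
    survival::Surv(y, event) ~ arm +
      survival::frailty(cluster, distribution = "gamma"),
    data = data)
  beta <- unname(stats::coef(fit)["arm"])
  se <- sqrt(fit$var[1, 1])
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = beta, se = se, lower = beta - z * se,
       upper = beta + z * se)
}
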