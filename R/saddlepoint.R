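#' Conditional-Bernoulli CGF model for a score set
#'
#' The within-cluster permutation law of the arm labels equals the law of
#' independent Bernoulli(p_i) variables X_ij conditioned on the cluster sums
#' sum_j X_ij = w_i.  This constructor extracts the tilt coefficients
#' a_ij = v_i w_ij, the nuisance probabilities p_i (default w_i/n_i, which
#' puts the denominator saddlepoint at the origin), the constraint targets
#' w_i, and the active-cluster mask.  Clusters with w_i in {0, n_i} or with
#' constant scores contribute a fixed amount to S; that offset is recorded
#' and removed from the active system.
#'
#' @param scores a `score_set`.
#' @param p optional vector of nuisance probabilities per cluster
#'   (defaults to w_i/n_i).
#' @return an object of class `cgf_model`.
#' @export
cgf_model <- function(scores, p = NULL) {
  stopifnot(inherits(scores, "score_set"))
  M <- scores$M
  if (is.null(p)) p <- scores$w_i / scores$n_i
  stopifnot(length(p) == M, all(p > 0 | scores$w_i == 0),
            all(p < 1 | scores$w_i == scores$n_i))
  a_all <- scores$v[scores$cluster] * scores$w
  rng <- vapply(split(a_all, scores$cluster),
                function(x) diff(range(x)), numeric(1))
  active <- scores$w_i > 0L & scores$w_i < scores$n_i & rng > 1e-12
  keep <- active[scores$cluster]
  offset <- sum((a_all * scores$zeta)[!keep])
  cl_active <- match(scores$cluster[keep], which(active))
  a_keep <- a_all[keep]
  w_act <- scores$w_i[active]
  split_mid <- vapply(seq_len(sum(active)), function(i) {
    ai <- sort(a_keep[cl_active == i], decreasing = TRUE)
    (ai[w_act[i]] + ai[w_act[i] + 1L]) / 2
  }, numeric(1))
  structure(list(
    split_mid = split_mid,
    a = a_all[keep],                     # tilt coefficients, active subjects
    cl = cl_active,                      # active-cluster index per subject
    m = sum(active),                     # number of active clusters
    p = p[active],
    n_i = scores$n_i[active],
    w_i = scores$w_i[active],
    offset = offset,                     # fixed contribution to S
    active = active), class = "cgf_model")
}

#' Joint cumulant generating function and derivative blocks
#'
#' Evaluates K(t, s) = sum_ij log(1 - p_i + p_i e^{t a_ij + s_i}) together
#' with its analytic gradient and the Hessian blocks needed by the
#' saddlepoint formulas.  The per-subject Bernoulli mean is computed in a
#' log-stable form, so there is no overflow for |t a_ij + s_i| up to ~700.
#' By cluster independence the s-block of the Hessian is diagonal.
#'
#' @param model a `cgf_model`.
#' @param t scalar tilt for the statistic.
#' @param s numeric vector of cluster tilts (length = active clusters).
#' @return list with `K`, `K_t`, `K_s`, `K_tt`, `K_ts`, `K_ss` (diagonal).
#' @export
cgf_eval <- function(model, t, s) {
  stopifnot(is.finite(t), all(is.finite(s)), length(s) == model$m)
  a <- model$a
  cl <- model$cl
  p <- model$p[cl]
  eta <- t * a + s[cl]
  mu <- stats::plogis(eta + stats::qlogis(p))
  q <- mu * (1 - mu)
  # log(1 - p + p e^eta), stable on both sides
  big <- eta > 0
  Kterm <- numeric(length(eta))
  Kterm[big] <- eta[big] + log(p[big] + (1 - p[big]) * exp(-eta[big]))
  Kterm[!big] <- log1p(p[!big] * expm1(eta[!big]))
  agg <- rowsum(cbind(mu, q, a * q), cl, reorder = TRUE)
  list(K = sum(Kterm),
       K_t = sum(a * mu),
       K_s = agg[, 1L],
       K_tt = sum(a * a * q),
       K_ts = agg[, 3L],
       K_ss = agg[, 2L])
}

# internal: solve the cluster equations sum_j mu_ij(t, s_i) = w_i for fixed t.
# Each equation is strictly increasing in s_i (a sum of logistics), so a
# per-cluster bracket is expanded first and safeguarded Newton/bisection is
# then run inside it, vectorised across clusters.  At large |t| the
# equations are near-staircases, which is why an unguarded Newton is not
# safe here.
solve_s_given_t <- function(model, t, s_init = NULL, tol = 1e-11,
                            max_iter = 200L) {
  # default start: s_i = -t * (midpoint between the w_i-th and (w_i+1)-th
  # largest coefficient), which puts exactly w_i subjects on the positive
  # side of the tilt -- essentially exact for large |t|, zero at t = 0
  s <- if (is.null(s_init)) -t * model$split_mid else s_init
  logit_p <- stats::qlogis(model$p[model$cl])
  ta <- t * model$a + logit_p
  w_i <- model$w_i
  cl <- model$cl
  fval <- function(s) {
    mu <- stats::plogis(ta + s[cl])
    agg <- rowsum(cbind(mu, mu * (1 - mu)), cl, reorder = TRUE)
    list(f = agg[, 1L] - w_i, fp = agg[, 2L])
  }
  # bracket each cluster equation around the start value
  lo <- hi <- s
  step <- rep(1, model$m)
  f_lo <- fval(lo)$f
  for (k in seq_len(120L)) {
    bad <- f_lo > 0
    if (!any(bad)) break
    lo[bad] <- lo[bad] - step[bad]
    step[bad] <- step[bad] * 2
    f_lo <- fval(lo)$f
  }
  step <- rep(1, model$m)
  f_hi <- fval(hi)$f
  for (k in seq_len(120L)) {
    bad <- f_hi < 0
    if (!any(bad)) break
    hi[bad] <- hi[bad] + step[bad]
    step[bad] <- step[bad] * 2
    f_hi <- fval(hi)$f
  }
  s <- (lo + hi) / 2
  res <- Inf
  for (it in seq_len(max_iter)) {
    cur <- fval(s)
    res <- max(abs(cur$f))
    if (res < tol * max(model$n_i)) break
    lo <- ifelse(cur$f < 0, s, lo)
    hi <- ifelse(cur$f > 0, s, hi)
    cand <- s - cur$f / pmax(cur$fp, 1e-300)
    mid <- (lo + hi) / 2
    s <- ifelse(cand > lo & cand < hi, cand, mid)
  }
  if (res >= max(1e-6, tol * max(model$n_i)) * 100)
    stop("inner saddle equations did not converge: residual ",
         signif(res, 3))
  list(s = s, iterations = it, residual = res)
}

#' Numerator saddlepoint
#'
#' Solves the (M+1)-equation gradient system
#' grad K(t, s) = (s_obs, w_1, ..., w_M)
#' by nested profiling: for fixed t every cluster tilt solves a monotone
#' one-dimensional equation (vectorised Newton); the profiled outer equation
#' in t is strictly increasing and solved by safeguarded Newton with a
#' bracketing fallback to bisection.  `s_obs` here is on the scale of the
#' active system, i.e. the observed statistic minus the fixed offset of
#' inactive clusters.
#'
#' @param model a `cgf_model`.
#' @param s_obs target for the statistic equation (active scale).
#' @param tol gradient residual tolerance (scaled by max(1, |s_obs|)).
#' @param max_iter maximum outer iterations.
#' @return list of class `saddle_solution` with `t_hat`, `s_hat`, the CGF
#'   value/derivative blocks at the solution, and convergence metadata.
#' @export
solve_numerator_saddle <- function(model, s_obs, tol = 1e-8, max_iter = 200L) {
  if (model$m == 0L) stop("no active clusters: degenerate system")
  sup <- saddle_support(model)
  if (s_obs <= sup[1L] + 1e-12 * max(1, abs(sup[1L])) ||
      s_obs >= sup[2L] - 1e-12 * max(1, abs(sup[2L])))
    stop("s_obs at or beyond the boundary of the attainable support; ",
         "use the boundary convention in dsa_midp")
  rtol <- tol * max(1, abs(s_obs))
  g_of <- function(t, s_init = NULL) {
    inner <- solve_s_given_t(model, t, s_init)
    ev <- cgf_eval(model, t, inner$s)
    list(g = ev$K_t - s_obs, s = inner$s, ev = ev)
  }
  fallback <- FALSE
  cur <- g_of(0)
  t <- 0
  # bracket the root of the strictly increasing profiled equation; each
  # probe tightens the bracket on its own side
  sch <- cur$ev$K_tt - sum(cur$ev$K_ts^2 / cur$ev$K_ss)
  scale <- 1 / sqrt(max(sch, 1e-12))
  if (cur$g < 0) {
    t_lo <- 0; g_lo <- cur$g
    t_hi <- NA; k <- 0
    repeat {
      k <- k + 1
      if (k > 90) stop("failed to bracket the numerator saddle")
      cand <- scale * 2^k
      gc <- g_of(cand)$g
      if (gc >= 0) { t_hi <- cand; g_hi <- gc; break }
      t_lo <- cand; g_lo <- gc
    }
  } else {
    t_hi <- 0; g_hi <- cur$g
    t_lo <- NA; k <- 0
    repeat {
      k <- k + 1
      if (k > 90) stop("failed to bracket the numerator saddle")
      cand <- -scale * 2^k
      gc <- g_of(cand)$g
      if (gc <= 0) { t_lo <- cand; g_lo <- gc; break }
      t_hi <- cand; g_hi <- gc
    }
  }
  it <- 0L
  repeat {
    it <- it + 1L
    if (abs(cur$g) <= rtol || it > max_iter) break
    sch <- cur$ev$K_tt - sum(cur$ev$K_ts^2 / cur$ev$K_ss)
    t_new <- if (sch > 0) t - cur$g / sch else NA_real_
    if (!is.finite(t_new) || t_new <= t_lo || t_new >= t_hi) {
      t_new <- (t_lo + t_hi) / 2          # bisection safeguard
      fallback <- TRUE
    }
    t <- t_new
    cur <- g_of(t, cur$s)
    if (cur$g < 0) { t_lo <- t; g_lo <- cur$g } else { t_hi <- t; g_hi <- cur$g }
  }
  if (abs(cur$g) > rtol)
    stop("numerator saddle did not converge: residual ", signif(cur$g, 3))
  structure(list(t_hat = t, s_hat = cur$s,
                 K = cur$ev$K, K_t = cur$ev$K_t, K_s = cur$ev$K_s,
                 K_tt = cur$ev$K_tt, K_ts = cur$ev$K_ts, K_ss = cur$ev$K_ss,
                 residual = abs(cur$g), iterations = it,
                 fallback = fallback), class = "saddle_solution")
}

#' Denominator saddlepoint (t = 0 system)
#'
#' With the default nuisance probabilities p_i = w_i/n_i the constraint
#' system at t = 0 is solved exactly by the zero vector.  For general p_i
#' the per-cluster equations have the closed-form solution
#' s_0i = logit(w_i/n_i) - logit(p_i).
#'
#' @param model a `cgf_model`.
#' @return numeric vector of cluster tilts (length = active clusters).
#' @export
denominator_saddle <- function(model) {
  stats::qlogis(model$w_i / model$n_i) - stats::qlogis(model$p)
}

#' Signed-root and curvature statistics of the double saddlepoint
#'
#' r~ = sgn(t^) sqrt(2[(K(0,s0) - w's0) - (K(t^,s^) - s_obs t^ - w's^)])
#' (the bracket clamped at zero against roundoff) and
#' u~ = t^ sqrt(det K''(t^,s^) / det K''_ss(0,s0)).  The determinant ratio
#' is evaluated through the arrow structure of the Hessian,
#' det K'' = (prod_i K_ss,ii) (K_tt - sum_i K_ts,i^2 / K_ss,ii),
#' accumulated in log space; the full (M+1)x(M+1) matrix is never formed.
#'
#' @param model a `cgf_model`.
#' @param num a `saddle_solution` from [solve_numerator_saddle()].
#' @param s0 denominator saddle from [denominator_saddle()].
#' @param s_obs statistic target on the active scale.
#' @return list with `r`, `u` and the log determinant ratio.
#' @export
r_u_statistics <- function(model, num, s0, s_obs) {
  ev0 <- cgf_eval(model, 0, s0)
  ell0 <- ev0$K - sum(model$w_i * s0)
  ell1 <- num$K - s_obs * num$t_hat - sum(model$w_i * num$s_hat)
  r2 <- 2 * (ell0 - ell1)
  r <- sign(num$t_hat) * sqrt(max(r2, 0))
  schur <- num$K_tt - sum(num$K_ts^2 / num$K_ss)
  if (schur <= 0) stop("degenerate curvature at the numerator saddle")
  logratio <- sum(log(num$K_ss)) + log(schur) - sum(log(ev0$K_ss))
  u <- num$t_hat * exp(0.5 * logratio)
  list(r = r, u = u, log_det_ratio = logratio)
}

# internal: attainable range of the active-system statistic
saddle_support <- function(model) {
  lo <- hi <- 0
  for (i in seq_len(model$m)) {
    ai <- sort(model$a[model$cl == i])
    ni <- length(ai); wi <- model$w_i[i]
    lo <- lo + sum(ai[seq_len(wi)])
    hi <- hi + sum(ai[seq.int(ni - wi + 1L, ni)])
  }
  c(lo, hi)
}

# internal: standardized third cumulant of the profiled (conditional) CGF at
# t = 0, by central finite differences of the profiled mean function; used
# for the small-t limit of the tail formula.
profiled_lambda3 <- function(model) {
  ev0 <- cgf_eval(model, 0, denominator_saddle(model))
  kappa2 <- ev0$K_tt - sum(ev0$K_ts^2 / ev0$K_ss)
  h <- 0.1 / sqrt(max(kappa2, 1e-12))
  gplus <- cgf_eval(model, h, solve_s_given_t(model, h)$s)$K_t
  gminus <- cgf_eval(model, -h, solve_s_given_t(model, -h)$s)$K_t
  kappa3 <- (gplus - 2 * ev0$K_t + gminus) / h^2
  kappa3 / kappa2^1.5
}

#' Double saddlepoint mid-p-value
#'
#' Approximates the permutation mid-p, P(S > s_obs) + P(S = s_obs)/2, by the
#' Lugannani-Rice-type tail formula
#' 1 - Phi(r~) + phi(r~)(1/u~ - 1/r~).
#' The lower-tail value is obtained by applying the same machinery to the
#' negated tilt coefficients; the two-sided value is
#' min(1, 2 min(upper, lower)).
#'
#' Near-singular regime: when |t^| < 1e-5 the catastrophic difference
#' 1/u~ - 1/r~ is replaced by its analytic limit -lambda3/6, where lambda3
#' is the standardized third cumulant of the profiled conditional CGF at the
#' origin (so the value tends to 1/2 plus a skewness correction).  Boundary
#' convention: when s_obs sits at the support maximum the upper mid-p is
#' P(S = max)/2, taken from exact enumeration when the space is small enough
#' and otherwise reported as 0 with a warning; the minimum is handled
#' symmetrically.
#'
#' @param scores a `score_set`.
#' @param side "upper", "lower" or "two.sided".
#' @param t_tol threshold on |t^| for the small-tilt series.
#' @param max_space enumeration cap for the boundary atom.
#' @return mid-p-value with attribute `diagnostics`.
#' @export
dsa_midp <- function(scores, side = c("two.sided", "upper", "lower"),
                     t_tol = 1e-5, max_space = 2e6) {
  side <- match.arg(side)
  model <- cgf_model(scores)
  if (model$m == 0L)
    stop("degenerate permutation distribution: no active clusters")
  target <- observed_statistic(scores) - model$offset
  if (side == "upper") return(dsa_one_side(model, target, t_tol, max_space))
  neg <- negate_cgf_model(model)
  if (side == "lower") return(dsa_one_side(neg, -target, t_tol, max_space))
  up <- dsa_one_side(model, target, t_tol, max_space)
  lo <- dsa_one_side(neg, -target, t_tol, max_space)
  out <- min(1, 2 * min(up, lo))
  attr(out, "diagnostics") <- list(upper = attr(up, "diagnostics"),
                                   lower = attr(lo, "diagnostics"))
  out
}

negate_cgf_model <- function(model) {
  model$a <- -model$a
  model$offset <- -model$offset
  model$split_mid <- vapply(seq_len(model$m), function(i) {
    ai <- sort(model$a[model$cl == i], decreasing = TRUE)
    (ai[model$w_i[i]] + ai[model$w_i[i] + 1L]) / 2
  }, numeric(1))
  model
}

# internal: exact active-system distribution from the model itself (used
# only for boundary atoms; mirrors exact_distribution on the active scale)
model_distribution <- function(model, max_space = 2e6) {
  values <- 0
  for (i in seq_len(model$m)) {
    ai <- model$a[model$cl == i]
    cmb <- utils::combn(length(ai), model$w_i[i])
    cs <- colSums(matrix(ai[cmb], nrow = model$w_i[i]))
    if (length(values) * length(cs) > max_space)
      stop("space too large")
    values <- as.vector(outer(values, cs, "+"))
  }
  values
}

# internal: upper mid-p of the active system at the given target
dsa_one_side <- function(model, target, t_tol, max_space) {
  sup <- saddle_support(model)
  btol <- 1e-9 * max(1, max(abs(sup)))
  diag <- list(boundary = FALSE, small_t = FALSE, fallback = FALSE)
  if (target >= sup[2L] - btol || target <= sup[1L] + btol) {
    diag$boundary <- TRUE
    atomp <- tryCatch({
      vals <- model_distribution(model, max_space)
      edge <- if (target >= sup[2L] - btol) max(vals) else min(vals)
      mean(abs(vals - edge) <= 1e-9)
    }, error = function(e) {
      warning("boundary atom probability not enumerable; reporting 0")
      0
    })
    out <- if (target >= sup[2L] - btol) 0.5 * atomp else 1 - 0.5 * atomp
    attr(out, "diagnostics") <- diag
    return(out)
  }
  num <- solve_numerator_saddle(model, target)
  s0 <- denominator_saddle(model)
  ru <- r_u_statistics(model, num, s0, target)
  diag$fallback <- num$fallback
  diag$iterations <- num$iterations
  diag$residual <- num$residual
  diag$t_hat <- num$t_hat
  if (abs(num$t_hat) < t_tol) {
    diag$small_t <- TRUE
    corr <- -profiled_lambda3(model) / 6
    out <- 1 - stats::pnorm(ru$r) + stats::dnorm(ru$r) * corr
  } else {
    out <- 1 - stats::pnorm(ru$r) +
      stats::dnorm(ru$r) * (1 / ru$u - 1 / ru$r)
  }
  out <- min(max(out, 0), 1)
  attr(out, "diagnostics") <- diag
  out
}
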