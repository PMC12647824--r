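#' Observed linear rank statistic
#'
#' S = sum_i v_i sum_j w_ij zeta_ij.
#'
#' @param scores a `score_set`.
#' @return numeric scalar.
#' @export
observed_statistic <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  sum(scores$v[scores$cluster] * scores$w * scores$zeta)
}

#' Permutation mean and variance of the statistic
#'
#' Exact first two moments of S under independent within-cluster
#' permutation of the arm labels with group sizes fixed:
#' mean = sum_i v_i (w_i/n_i) sum_j w_ij and
#' variance = sum_i v_i^2 w_i(n_i - w_i)/(n_i(n_i - 1)) sum_j (w_ij - wbar_i)^2.
#' Clusters with n_i = 1 or w_i in {0, n_i} contribute nothing to the
#' variance.
#'
#' @param scores a `score_set`.
#' @return list with `mean` and `var`.
#' @export
permutation_moments <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  cl <- scores$cluster
  n_i <- scores$n_i; w_i <- scores$w_i; v <- scores$v
  sum_w <- as.vector(rowsum(scores$w, cl))
  mbar <- sum_w / n_i
  ss <- as.vector(rowsum((scores$w - mbar[cl])^2, cl))
  mean <- sum(v * (w_i / n_i) * sum_w)
  active <- n_i > 1L & w_i > 0L & w_i < n_i
  var <- sum((v^2 * w_i * (n_i - w_i) / (n_i * pmax(n_i - 1L, 1L)) * ss)[active])
  list(mean = mean, var = var)
}

#' Asymptotic-normal mid-p-value
#'
#' Normal approximation to the permutation distribution using the exact
#' permutation mean and variance; no continuity correction.  The two-sided
#' value follows the package-wide rule min(1, 2 min(upper, lower)).
#'
#' @param scores a `score_set`.
#' @param side "upper", "lower" or "two.sided".
#' @return mid-p-value.
#' @export
an_midp <- function(scores, side = c("two.sided", "upper", "lower")) {
  side <- match.arg(side)
  mom <- permutation_moments(scores)
  if (mom$var <= 0) stop("degenerate permutation distribution")
  z <- (observed_statistic(scores) - mom$mean) / sqrt(mom$var)
  up <- stats::pnorm(z, lower.tail = FALSE)
  switch(side, upper = up, lower = 1 - up,
         two.sided = min(1, 2 * min(up, 1 - up)))
}

#' Draw one uniformly random within-cluster arm assignment
#'
#' Within each cluster exactly w_i subjects receive arm 1; clusters are
#' permuted independently.  Uses the current R random number stream.
#'
#' @param scores a `score_set`.
#' @return integer 0/1 vector aligned with `scores$w`.
#' @export
sample_within_cluster_permutation <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  zeta <- integer(length(scores$w))
  idx <- split(seq_along(scores$cluster), scores$cluster)
  for (i in seq_len(scores$M)) {
    wi <- scores$w_i[i]
    ni <- scores$n_i[i]
    if (wi > 0L) {
      pick <- if (wi == ni) idx[[i]] else idx[[i]][sample.int(ni, wi)]
      zeta[pick] <- 1L
    }
  }
  zeta
}

## internal: per-cluster enumeration of assignment sums ----------------------

# v_i-weighted score sums for every within-cluster choice of w_i treated
# subjects; clusters with w_i in {0, n_i} are deterministic and folded into
# the scalar offset.
cluster_assignment_sums <- function(scores, active_only = TRUE) {
  cl <- scores$cluster
  wsplit <- split(scores$w, cl)
  zsplit <- split(scores$zeta, cl)
  sums <- vector("list", scores$M)
  offset <- 0
  active <- logical(scores$M)
  for (i in seq_len(scores$M)) {
    wi <- scores$w_i[i]; ni <- scores$n_i[i]
    wv <- wsplit[[i]] * scores$v[i]
    if (wi == 0L || wi == ni) {
      offset <- offset + sum(wv * zsplit[[i]])
      next
    }
    cmb <- utils::combn(ni, wi)
    sums[[i]] <- colSums(matrix(wv[cmb], nrow = wi))
    active[i] <- TRUE
  }
  list(sums = sums[active], offset = offset, active = active)
}

#' Monte Carlo permutation mid-p-value
#'
#' mid-p = B^{-1} (sum_b I(S_b > S_obs) + 1/2 sum_b I(S_b = S_obs)),
#' equality judged with absolute tolerance 1e-9 on the statistic scale.
#'
#' @param scores a `score_set`.
#' @param B number of permutations (>= 1).
#' @param side "upper", "lower" or "two.sided".
#' @param seed optional integer seed for reproducibility.
#' @return mid-p-value with attribute `B`.
#' @export
mcp_midp <- function(scores, B = 1e4, side = c("two.sided", "upper", "lower"),
                     seed = NULL) {
  side <- match.arg(side)
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  s_obs <- observed_statistic(scores)
  ca <- cluster_assignment_sums(scores)
  S_b <- rep(ca$offset, B)
  for (cs in ca$sums)
    S_b <- S_b + cs[sample.int(length(cs), B, replace = TRUE)]
  tol <- 1e-9
  eq <- abs(S_b - s_obs) <= tol
  up <- (sum(S_b > s_obs + tol) + 0.5 * sum(eq)) / B
  lo <- (sum(S_b < s_obs - tol) + 0.5 * sum(eq)) / B
  out <- switch(side, upper = up, lower = lo,
                two.sided = min(1, 2 * min(up, lo)))
  attr(out, "B") <- B
  out
}

#' Exact-enumeration mid-p-value
#'
#' Enumerates the full product space of within-cluster assignments
#' (clusters in input order, per-cluster combinations in lexicographic
#' order) and evaluates the mid-p exactly.  Serves as the ground-truth
#' oracle for the saddlepoint and Monte Carlo engines.
#'
#' @param scores a `score_set`.
#' @param side "upper", "lower" or "two.sided".
#' @param max_space refuse enumeration beyond this many assignments.
#' @return mid-p-value with attribute `space` (number of assignments).
#' @export
exact_midp <- function(scores, side = c("two.sided", "upper", "lower"),
                       max_space = 2e6) {
  side <- match.arg(side)
  s_obs <- observed_statistic(scores)
  dist <- exact_distribution(scores, max_space)
  tol <- 1e-9
  eq <- abs(dist$values - s_obs) <= tol
  up <- (sum(dist$values > s_obs + tol) + 0.5 * sum(eq)) / length(dist$values)
  lo <- (sum(dist$values < s_obs - tol) + 0.5 * sum(eq)) / length(dist$values)
  out <- switch(side, upper = up, lower = lo,
                two.sided = min(1, 2 * min(up, lo)))
  attr(out, "space") <- length(dist$values)
  out
}

# internal: all attainable values of S (equally likely, with multiplicity)
exact_distribution <- function(scores, max_space = 2e6) {
  ca <- cluster_assignment_sums(scores)
  space <- prod(vapply(ca$sums, length, numeric(1)))
  if (space > max_space)
    stop("permutation space of size ", format(space, scientific = TRUE),
         " exceeds max_space; use the Monte Carlo engine (mcp_midp)")
  values <- ca$offset
  for (cs in ca$sums)
    values <- as.vector(outer(values, cs, "+"))
  list(values = values, space = space)
}
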