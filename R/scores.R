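#' Mid-ranks
#'
#' Ranks 1..N with tied values assigned the average of the ranks they span,
#' so the rank sum is always N(N+1)/2.
#'
#' @param x numeric vector, all finite.
#' @return numeric vector of mid-ranks.
#' @export
midrank <- function(x) {
  if (length(x) == 0L) stop("empty input")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite value at index ", bad[1L])
  rank(x, ties.method = "average")
}

## internal: score-set container --------------------------------------------

#' Attach cluster weights and optional centering to raw scores
#'
#' Builds the `score_set` object consumed by every p-value engine: per
#' cluster it records the size n_i, the treated count w_i and the cluster
#' weight v_i (1 for `unit`, 1/(n_i+1) for `wilcoxon_type`); per subject the
#' fixed score w_ij and the arm indicator.  With `center = TRUE` the scores
#' are replaced by their within-cluster deviations so the permutation mean
#' of the statistic is exactly zero.
#'
#' @param cluster cluster identifier per subject (any atomic type).
#' @param w numeric score per subject.
#' @param zeta binary arm indicator per subject.
#' @param v_rule "unit" or "wilcoxon_type".
#' @param center logical; center scores within cluster (default TRUE).
#' @param test character label stored as metadata.
#' @return an object of class `score_set`.
#' @export
assemble_scores <- function(cluster, w, zeta,
                            v_rule = c("unit", "wilcoxon_type"),
                            center = TRUE, test = "custom") {
  v_rule <- match.arg(v_rule)
  if (length(w) != length(cluster) || length(zeta) != length(cluster))
    stop("cluster, w and zeta must have equal length")
  if (!all(is.finite(w))) stop("non-finite score")
  if (!all(zeta %in% c(0, 1))) stop("zeta must be binary 0/1")
  fac <- factor(cluster, levels = unique(cluster))
  cl <- as.integer(fac)
  M <- nlevels(fac)
  n_i <- tabulate(cl, nbins = M)
  w_i <- as.vector(rowsum(as.numeric(zeta), cl))
  v <- switch(v_rule, unit = rep(1, M), wilcoxon_type = 1 / (n_i + 1))
  if (center) {
    mbar <- as.vector(rowsum(w, cl)) / n_i
    w <- w - mbar[cl]
  }
  structure(list(cluster = cl, w = w, zeta = as.integer(zeta),
                 v = v, n_i = n_i, w_i = as.integer(round(w_i)),
                 M = M, cluster_labels = levels(fac),
                 test = test, v_rule = v_rule, centered = center),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("score_set:", x$test, "|", x$M, "clusters,", length(x$w),
      "subjects | v_rule =", x$v_rule,
      if (x$centered) "| centered\n" else "\n")
  invisible(x)
}

## Datta-Satten rank-sum scores ---------------------------------------------

#' Datta-Satten cluster-adjusted rank scores
#'
#' For subject j of cluster i the score is
#' \deqn{w_{ij} = 1 + \tfrac12 \sum_{k \ne i} (F_k(y_{ij}) + F_k(y_{ij}^-))}
#' where F_k is the empirical distribution function of cluster k's outcomes
#' and F_k(.^-) its left limit.  Scores lie in [1, M].  With censored data
#' the formula is applied to the observed times, ignoring event indicators.
#'
#' @param data clustered two-sample data (see [as_clustered_data()]).
#' @return list with per-subject `w`, `cluster`, `zeta`.
#' @export
ds_scores <- function(data) {
  data <- as_clustered_data(data)
  fac <- factor(data$cluster, levels = unique(data$cluster))
  cl <- as.integer(fac)
  M <- nlevels(fac)
  y <- data$y
  # G_k(y) = (F_k(y) + F_k(y-)) / 2 = (#{<y} + #{<=y}) / (2 n_k)
  tot <- numeric(length(y))
  own <- numeric(length(y))
  for (k in seq_len(M)) {
    yk <- sort(y[cl == k])
    gk <- (findInterval(y, yk) + findInterval(y, yk, left.open = TRUE)) /
      (2 * length(yk))
    tot <- tot + gk
    own[cl == k] <- gk[cl == k]
  }
  list(w = 1 + (tot - own), cluster = data$cluster, zeta = data$arm)
}

## clustered Wilcoxon signed-rank scores ------------------------------------

#' Clustered Wilcoxon signed-rank scores
#'
#' Scores are the pooled mid-ranks of |D_ij| and the "arm" indicator is
#' I(D_ij > 0); within-cluster permutation then re-assigns the signs with
#' the per-cluster count of positives held fixed.  Differences exactly zero
#' are dropped before ranking under `zero_policy = "drop"`; under
#' `"keep"` they are retained in the ranking (so they still affect the
#' mid-ranks of the others) but are isolated in singleton pseudo-clusters
#' with zeta = 0, where they contribute a constant and never randomise.
#'
#' @param data clustered paired data (see [as_paired_data()]).
#' @param zero_policy "drop" (default) or "keep".
#' @return list with per-subunit `w`, `cluster`, `zeta`.
#' @export
wsr_scores <- function(data, zero_policy = c("drop", "keep")) {
  zero_policy <- match.arg(zero_policy)
  data <- as_paired_data(data)
  d <- data$d
  zero <- d == 0
  if (all(zero)) stop("degenerate paired data: all differences zero")
  cluster <- as.character(data$cluster)
  if (zero_policy == "drop") {
    d <- d[!zero]
    cluster <- cluster[!zero]
  } else if (any(zero)) {
    cluster[zero] <- paste0(".zero", seq_len(sum(zero)))
  }
  list(w = midrank(abs(d)), cluster = cluster, zeta = as.integer(d > 0))
}

## weighted logrank scores --------------------------------------------------

#' Weighted logrank per-subject scores for right-censored clustered data
#'
#' Observed-minus-expected event contributions accumulated over the pooled
#' risk sets: for subject with observed time y and event indicator delta,
#' \deqn{w = \delta W(y) - \sum_{t_k \le y} W(t_k) d_k / Y(t_k)}
#' where t_k are the distinct pooled event times, d_k the pooled event
#' counts, Y(t) the pooled number at risk, and the scalar weight W(t) is 1
#' (logrank), Y(t)/N (Gehan-Wilcoxon) or the left-continuous pooled
#' Kaplan-Meier estimate (Prentice-Wilcoxon).  The scores always sum to
#' zero over all subjects.
#'
#' @param data clustered survival data with an `event` column.
#' @param weight "lr", "gw" or "pw".
#' @return list with per-subject `w`, `cluster`, `zeta`.
#' @export
survival_scores <- function(data, weight = c("lr", "gw", "pw")) {
  weight <- match.arg(weight)
  data <- as_clustered_data(data)
  if (any(data$y < 0)) stop("negative survival times")
  if (sum(data$event) == 0) stop("no events: scores are undefined")
  y <- data$y
  N <- length(y)
  et <- sort(unique(y[data$event == 1]))
  d_k <- vapply(et, function(t) sum(y == t & data$event == 1), numeric(1))
  Y_k <- vapply(et, function(t) sum(y >= t), numeric(1))
  W_k <- switch(weight,
    lr = rep(1, length(et)),
    gw = Y_k / N,
    # left-continuous pooled Kaplan-Meier: S-(t_1) = 1
    pw = cumprod(c(1, (1 - d_k / Y_k)))[seq_along(et)])
  # cumulative hazard-type increment sum_{t_k <= y} W_k d_k / Y_k
  cumA <- cumsum(W_k * d_k / Y_k)
  idx <- findInterval(y, et)           # number of event times <= y
  A <- ifelse(idx > 0, cumA[pmax(idx, 1L)], 0)
  own <- numeric(N)
  has <- data$event == 1
  own[has] <- W_k[match(y[has], et)]
  list(w = own - A, cluster = data$cluster, zeta = data$arm)
}

## convenience front end -----------------------------------------------------

#' Build the score set for a named clustered rank test
#'
#' @param data two-sample data for tests "ds", "lr", "gw", "pw"; paired
#'   data for "wsr".
#' @param test test name.
#' @param v_rule cluster weight rule, "unit" (default) or "wilcoxon_type".
#' @param center center scores within clusters (default TRUE).
#' @param zero_policy zero-difference policy for "wsr".
#' @return a `score_set`.
#' @export
clustered_scores <- function(data, test = c("ds", "lr", "gw", "pw", "wsr"),
                             v_rule = c("unit", "wilcoxon_type"),
                             center = TRUE,
                             zero_policy = c("drop", "keep")) {
  test <- match.arg(test)
  raw <- switch(test,
    ds  = ds_scores(data),
    wsr = wsr_scores(data, zero_policy = zero_policy),
    survival_scores(data, weight = test))
  assemble_scores(raw$cluster, raw$w, raw$zeta, v_rule = v_rule,
                  center = center, test = test)
}
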