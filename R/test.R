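#' Rank-based test for clustered data
#'
#' End-to-end driver: builds the fixed rank scores for the requested test,
#' then computes the observed statistic, the exact permutation moments, and
#' mid-p-values from each requested engine.  Engines: `"an"` asymptotic
#' normal, `"dsa"` double saddlepoint approximation, `"mcp"` Monte Carlo
#' permutation, `"exact"` full enumeration (small problems only).
#'
#' @param data two-sample data for tests "ds"/"lr"/"gw"/"pw", paired data
#'   for "wsr".
#' @param test test name.
#' @param engine character vector of engines to run.
#' @param side "two.sided" (default), "upper" or "lower".
#' @param B Monte Carlo permutations for the "mcp" engine.
#' @param seed optional integer seed (recorded in the result).
#' @param v_rule,center,zero_policy passed to [clustered_scores()].
#' @param max_space enumeration cap for the "exact" engine.
#' @return object of class `saddlerank_test`: observed statistic,
#'   permutation moments, one mid-p per engine, and diagnostics.
#' @export
cluster_rank_test <- function(data, test = c("ds", "lr", "gw", "pw", "wsr"),
                              engine = c("dsa", "an"),
                              side = c("two.sided", "upper", "lower"),
                              B = 1e4, seed = NULL,
                              v_rule = c("unit", "wilcoxon_type"),
                              center = TRUE,
                              zero_policy = c("drop", "keep"),
                              max_space = 2e6) {
  test <- match.arg(test)
  side <- match.arg(side)
  engine <- match.arg(engine, c("dsa", "an", "mcp", "exact"),
                      several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  sc <- clustered_scores(data, test = test, v_rule = v_rule,
                         center = center, zero_policy = zero_policy)
  mom <- permutation_moments(sc)
  midp <- list()
  diagnostics <- list(seed = seed, B = B)
  for (e in engine) {
    midp[[e]] <- switch(e,
      an = an_midp(sc, side),
      dsa = {
        p <- dsa_midp(sc, side, max_space = max_space)
        diagnostics$dsa <- attr(p, "diagnostics")
        as.numeric(p)
      },
      mcp = {
        p <- mcp_midp(sc, B = B, side = side)
        diagnostics$mcp_B <- attr(p, "B")
        as.numeric(p)
      },
      exact = {
        p <- exact_midp(sc, side, max_space = max_space)
        diagnostics$exact_space <- attr(p, "space")
        as.numeric(p)
      })
  }
  structure(list(test = test, side = side,
                 s_obs = observed_statistic(sc),
                 perm_mean = mom$mean, perm_var = mom$var,
                 midp = midp, scores = sc,
                 diagnostics = diagnostics),
            class = "saddlerank_test")
}

#' @export
print.saddlerank_test <- function(x, ...) {
  cat("Clustered rank test:", toupper(x$test),
      "(", x$scores$M, "clusters )\n")
  cat(sprintf("  S_obs = %.6g | perm mean = %.6g | perm sd = %.6g\n",
              x$s_obs, x$perm_mean, sqrt(x$perm_var)))
  for (e in names(x$midp))
    cat(sprintf("  mid-p [%s, %s] = %.6g\n", e, x$side, x$midp[[e]]))
  invisible(x)
}
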