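# Random small clustered score-set instances for property tests.  Pooled
# mid-ranked outcomes (ties induced by rounding), random treated counts,
# centered scores -- the configuration every p-value engine consumes.
random_score_set <- function(M = sample(2:5, 1),
                             n = sample(2:5, M, replace = TRUE),
                             ties = TRUE) {
  cl <- rep(seq_len(M), n)
  y <- stats::rnorm(sum(n))
  if (ties) y <- round(y, 1)
  w <- midrank(y)
  wi <- vapply(n, function(ni) sample.int(ni - 1L, 1L), integer(1))
  zeta <- unlist(lapply(seq_len(M), function(i)
    sample(rep(c(1L, 0L), c(wi[i], n[i] - wi[i])))), use.names = FALSE)
  assemble_scores(cl, w, zeta, center = TRUE, test = "ds")
}

# brute-force weighted-logrank score by the defining risk-set sum
brute_logrank_scores <- function(y, event, weight = "lr") {
  N <- length(y)
  et <- sort(unique(y[event == 1]))
  d <- vapply(et, function(t) sum(y == t & event == 1), numeric(1))
  Yk <- vapply(et, function(t) sum(y >= t), numeric(1))
  W <- switch(weight, lr = rep(1, length(et)), gw = Yk / N,
              pw = cumprod(c(1, 1 - d / Yk))[seq_along(et)])
  vapply(seq_len(N), function(s) {
    sum(vapply(seq_along(et), function(k) {
      if (et[k] > y[s]) return(0)
      dN <- as.numeric(y[s] == et[k] && event[s] == 1)
      W[k] * (dN - d[k] / Yk[k] * as.numeric(y[s] >= et[k]))
    }, numeric(1)))
  }, numeric(1))
}
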