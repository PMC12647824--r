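test_that("midrank matches hand-enumerated ranks and the rank-sum identity", {
  expect_equal(midrank(c(3.1, 1.2, 2.0)), c(3, 1, 2))
  expect_equal(midrank(c(5, 5, 5)), c(2, 2, 2))
  expect_equal(midrank(c(1, 2, 2, 7)), c(1, 2.5, 2.5, 4))
  set.seed(1)
  for (i in 1:20) {
    x <- round(rnorm(sample(1:40, 1)), 1)
    expect_equal(sum(midrank(x)), length(x) * (length(x) + 1) / 2)
  }
  expect_error(midrank(c(1, NA, 3)), "index 2")
  expect_error(midrank(numeric(0)), "empty")
})

test_that("Datta-Satten scores follow the between-cluster EDF construction", {
  # single cluster: empty sum over other clusters
  one <- data.frame(cluster = 1, y = c(3, 9, 1), arm = c(0, 1, 0))
  expect_equal(ds_scores(one)$w, rep(1, 3))
  # two singleton clusters, direct EDF evaluation
  two <- data.frame(cluster = c(1, 2), y = c(1, 2), arm = c(0, 1))
  expect_equal(ds_scores(two)$w, c(1, 2))
  # cross-cluster tie exercises the left limit
  tie <- data.frame(cluster = c(1, 1, 2), y = c(1, 3, 3), arm = c(0, 1, 0))
  expect_equal(ds_scores(tie)$w[2], 1.5)
  # scores always lie in [1, M]
  set.seed(2)
  for (i in 1:10) {
    M <- sample(2:6, 1)
    dat <- data.frame(cluster = rep(1:M, each = 3),
                      y = round(rnorm(3 * M), 1),
                      arm = rbinom(3 * M, 1, 0.5))
    w <- ds_scores(dat)$w
    expect_true(all(w >= 1 - 1e-12 & w <= M + 1e-12))
  }
})

test_that("DS scores are invariant to cluster relabeling and record order", {
  set.seed(3)
  dat <- data.frame(cluster = rep(1:4, times = c(3, 2, 4, 3)),
                    y = round(rnorm(12), 1), arm = rbinom(12, 1, 0.5))
  base <- ds_scores(dat)$w
  perm <- sample(nrow(dat))
  shuf <- dat[perm, ]
  shuf$cluster <- paste0("c", shuf$cluster)  # relabel too
  expect_equal(ds_scores(shuf)$w, base[perm])
})

test_that("signed-rank scores pool mid-ranks of |d| and flag positives", {
  p1 <- data.frame(cluster = c(1, 1), subunit = 1:2, d = c(2, -1))
  s1 <- wsr_scores(p1)
  expect_equal(s1$w, c(2, 1))
  expect_equal(s1$zeta, c(1L, 0L))
  s2 <- wsr_scores(data.frame(cluster = c(1, 1), subunit = 1:2,
                              d = c(1, -1)))
  expect_equal(s2$w, c(1.5, 1.5))
  expect_equal(s2$zeta, c(1L, 0L))
  s3 <- wsr_scores(data.frame(cluster = c(1, 1), subunit = 1:2,
                              d = c(0, 3)), zero_policy = "drop")
  expect_equal(s3$w, 1)
  expect_equal(s3$zeta, 1L)
  expect_error(wsr_scores(data.frame(cluster = 1:2, subunit = c(1, 1),
                                     d = c(0, 0))), "degenerate")
})

test_that("kept zero differences stay fixed and never randomise", {
  dat <- data.frame(cluster = c(1, 1, 1), subunit = 1:3, d = c(0, 2, -1))
  ss <- clustered_scores(dat, "wsr", zero_policy = "keep")
  # the zero moved to its own pseudo-cluster with zeta = 0
  expect_equal(sum(ss$n_i == 1 & ss$w_i == 0), 1)
  # and it still influenced the pooled ranks of the others
  drop_ss <- clustered_scores(dat, "wsr", zero_policy = "drop")
  expect_false(isTRUE(all.equal(sort(abs(ss$w)), sort(abs(drop_ss$w)))))
})

test_that("weighted logrank scores match the risk-set oracle and sum to zero", {
  # hand example: times 1, 2, both events, one cluster
  dat <- data.frame(cluster = c(1, 1), y = c(1, 2), event = c(1, 1),
                    arm = c(1, 0))
  expect_equal(survival_scores(dat, "lr")$w, c(0.5, -0.5))
  expect_equal(survival_scores(dat, "gw")$w,
               brute_logrank_scores(dat$y, dat$event, "gw"))
  set.seed(4)
  for (i in 1:12) {
    n <- sample(5:14, 1)
    y <- round(rexp(n, 0.2), 1) + 0.1
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) == 0) ev[1] <- 1L
    dat <- data.frame(cluster = rep_len(1:3, n), y = y, event = ev,
                      arm = rbinom(n, 1, 0.5))
    for (wt in c("lr", "gw", "pw")) {
      sc <- survival_scores(dat, wt)
      expect_equal(sc$w, brute_logrank_scores(y, ev, wt), tolerance = 1e-10)
      expect_lt(abs(sum(sc$w)), 1e-10)
    }
  }
  expect_error(survival_scores(
    data.frame(cluster = 1, y = c(1, 2), event = c(0, 0), arm = c(0, 1))),
    "no events")
  expect_error(survival_scores(
    data.frame(cluster = 1, y = c(-1, 2), event = c(1, 1), arm = c(0, 1))),
    "negative")
})

test_that("Prentice-Wilcoxon weight equals the left-continuous Kaplan-Meier", {
  skip_if_not_installed("survival")
  set.seed(5)
  y <- round(rexp(30, 0.2), 1) + 0.1
  ev <- rbinom(30, 1, 0.7)
  km <- survival::survfit(survival::Surv(y, ev) ~ 1)
  et <- sort(unique(y[ev == 1]))
  Sminus <- vapply(et, function(t) {
    i <- km$time < t
    if (!any(i)) 1 else min(km$surv[i])
  }, numeric(1))
  dat <- data.frame(cluster = rep_len(1:5, 30), y = y, event = ev,
                    arm = rbinom(30, 1, 0.5))
  # rebuild the scores with the survfit-based weight and compare
  d_k <- vapply(et, function(t) sum(y == t & ev == 1), numeric(1))
  Y_k <- vapply(et, function(t) sum(y >= t), numeric(1))
  cumA <- cumsum(Sminus * d_k / Y_k)
  idx <- findInterval(y, et)
  ref <- ifelse(ev == 1, Sminus[match(y, et)], 0)
  ref[is.na(ref)] <- 0
  ref <- ref - ifelse(idx > 0, cumA[pmax(idx, 1)], 0)
  expect_equal(survival_scores(dat, "pw")$w, ref, tolerance = 1e-10)
})

test_that("assemble_scores applies cluster weights and centering", {
  ss <- assemble_scores(rep(1:2, c(4, 3)), 1:7, c(1, 0, 0, 1, 1, 0, 0),
                        v_rule = "unit", center = FALSE)
  expect_equal(ss$v, c(1, 1))
  ssw <- assemble_scores(rep(1:2, c(4, 3)), 1:7, c(1, 0, 0, 1, 1, 0, 0),
                         v_rule = "wilcoxon_type", center = FALSE)
  expect_equal(ssw$v, c(1 / 5, 1 / 4))  # v_i = 1/(n_i + 1), n = 4 gives 0.2
  cc <- assemble_scores(rep(1, 3), c(1, 2, 3), c(1, 0, 0), center = TRUE)
  expect_equal(cc$w, c(-1, 0, 1))
  # centered cluster sums vanish
  set.seed(6)
  ss <- random_score_set()
  expect_lt(max(abs(rowsum(ss$w, ss$cluster))), 1e-10)
})
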