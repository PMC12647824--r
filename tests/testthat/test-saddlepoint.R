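test_that("joint CGF vanishes at the origin and matches finite differences", {
  set.seed(21)
  ss <- random_score_set(M = 4)
  model <- cgf_model(ss)
  at0 <- cgf_eval(model, 0, numeric(model$m))
  expect_equal(at0$K, 0)
  # with p_i = w_i/n_i the s-gradient at the origin is w_i
  expect_equal(unname(at0$K_s), as.numeric(model$w_i))
  # general p_i: gradient at origin is n_i p_i
  p <- runif(ss$M, 0.2, 0.8)
  mg <- cgf_model(ss, p = p)
  expect_equal(unname(cgf_eval(mg, 0, numeric(mg$m))$K_s),
               mg$n_i * mg$p)
  # finite-difference oracle at random tilts
  h <- 1e-5
  for (i in 1:5) {
    t <- rnorm(1, sd = 0.3)
    s <- rnorm(model$m, sd = 0.3)
    ev <- cgf_eval(model, t, s)
    Kf <- function(t, s) cgf_eval(model, t, s)$K
    expect_equal(ev$K_t, (Kf(t + h, s) - Kf(t - h, s)) / (2 * h),
                 tolerance = 1e-5)
    expect_equal(ev$K_tt,
                 (Kf(t + h, s) - 2 * Kf(t, s) + Kf(t - h, s)) / h^2,
                 tolerance = 1e-4)
    for (j in seq_len(model$m)) {
      e <- replace(numeric(model$m), j, h)
      expect_equal(unname(ev$K_s[j]),
                   (Kf(t, s + e) - Kf(t, s - e)) / (2 * h),
                   tolerance = 1e-5)
      expect_equal(unname(ev$K_ss[j]),
                   (Kf(t, s + e) - 2 * Kf(t, s) + Kf(t, s - e)) / h^2,
                   tolerance = 1e-4)
    }
  }
})

test_that("numerator saddle solves the gradient system", {
  set.seed(22)
  for (i in 1:20) {
    ss <- random_score_set()
    model <- cgf_model(ss)
    sup <- saddlerank:::saddle_support(model)
    tgt <- runif(1, sup[1] + 0.1 * diff(sup), sup[2] - 0.1 * diff(sup))
    num <- solve_numerator_saddle(model, tgt)
    ev <- cgf_eval(model, num$t_hat, num$s_hat)
    expect_lt(abs(ev$K_t - tgt), 1e-8 * max(1, abs(tgt)))
    expect_lt(max(abs(ev$K_s - model$w_i)), 1e-7)
  }
  # permutation-mean target gives the zero tilt
  ss <- random_score_set(M = 3)
  model <- cgf_model(ss)
  mean0 <- cgf_eval(model, 0, numeric(model$m))$K_t
  num <- solve_numerator_saddle(model, mean0)
  expect_lt(abs(num$t_hat), 1e-8)
  # t_hat strictly increases with the target
  sup <- saddlerank:::saddle_support(model)
  grid <- seq(sup[1] + 0.15 * diff(sup), sup[2] - 0.15 * diff(sup),
              length.out = 7)
  th <- vapply(grid, function(g) solve_numerator_saddle(model, g)$t_hat,
               numeric(1))
  expect_true(all(diff(th) > 0))
  # boundary targets are refused
  expect_error(solve_numerator_saddle(model, sup[2]), "boundary")
})

test_that("denominator saddle is zero at empirical p and solves t=0 otherwise", {
  set.seed(23)
  ss <- random_score_set()
  model <- cgf_model(ss)
  expect_identical(denominator_saddle(model), rep(0, model$m))
  p <- runif(ss$M, 0.15, 0.85)
  mg <- cgf_model(ss, p = p)
  s0 <- denominator_saddle(mg)
  expect_lt(max(abs(cgf_eval(mg, 0, s0)$K_s - mg$w_i)), 1e-10)
  # single symmetric cluster
  sym <- assemble_scores(rep(1, 2), c(1, -1), c(1, 0), center = FALSE)
  expect_equal(denominator_saddle(cgf_model(sym, p = 0.5)), 0)
})

test_that("r/u statistics vanish at zero tilt, share signs, match dense determinants", {
  set.seed(24)
  ss <- random_score_set(M = 3)
  model <- cgf_model(ss)
  mean0 <- cgf_eval(model, 0, numeric(model$m))$K_t
  num <- solve_numerator_saddle(model, mean0)
  ru <- r_u_statistics(model, num, denominator_saddle(model), mean0)
  expect_equal(ru$r, 0, tolerance = 1e-6)
  expect_equal(ru$u, 0, tolerance = 1e-6)
  for (i in 1:15) {
    ss <- random_score_set()
    model <- cgf_model(ss)
    sup <- saddlerank:::saddle_support(model)
    tgt <- runif(1, sup[1] + 0.1 * diff(sup), sup[2] - 0.1 * diff(sup))
    num <- solve_numerator_saddle(model, tgt)
    s0 <- denominator_saddle(model)
    ru <- r_u_statistics(model, num, s0, tgt)
    if (abs(num$t_hat) > 1e-8) {
      expect_equal(sign(ru$r), sign(num$t_hat))
      expect_equal(sign(ru$u), sign(num$t_hat))
    }
    # arrow/log-space determinant ratio vs dense matrices
    ev <- cgf_eval(model, num$t_hat, num$s_hat)
    H <- matrix(0, model$m + 1, model$m + 1)
    H[1, 1] <- ev$K_tt
    H[1, -1] <- H[-1, 1] <- ev$K_ts
    diag(H)[-1] <- ev$K_ss
    dense <- det(H) / prod(cgf_eval(model, 0, s0)$K_ss)
    expect_equal(exp(ru$log_det_ratio), dense, tolerance = 1e-8)
  }
})

test_that("positive curvature holds at interior evaluation points", {
  set.seed(25)
  for (i in 1:10) {
    ss <- random_score_set()
    model <- cgf_model(ss)
    t <- rnorm(1, sd = 0.5)
    s <- rnorm(model$m, sd = 0.5)
    ev <- cgf_eval(model, t, s)
    expect_true(all(ev$K_ss > 0))
    expect_gt(ev$K_tt - sum(ev$K_ts^2 / ev$K_ss), 0)
  }
})

test_that("saddlepoint mid-p is complementary, scale invariant and monotone", {
  set.seed(26)
  for (i in 1:10) {
    ss <- random_score_set()
    up <- as.numeric(dsa_midp(ss, "upper"))
    lo <- as.numeric(dsa_midp(ss, "lower"))
    expect_equal(up + lo, 1, tolerance = 1e-9)
    # positive rescaling of scores leaves the mid-p unchanged
    ss2 <- ss
    ss2$w <- ss$w * 7.3
    expect_equal(as.numeric(dsa_midp(ss2, "upper")), up, tolerance = 1e-7)
  }
  # mid-p decreases as the observed statistic grows (same permutation law)
  ss <- random_score_set(M = 4, n = rep(4, 4))
  model <- cgf_model(ss)
  sup <- saddlerank:::saddle_support(model)
  grid <- seq(sup[1] + 0.1 * diff(sup), sup[2] - 0.1 * diff(sup),
              length.out = 9)
  pv <- vapply(grid, function(g)
    as.numeric(saddlerank:::dsa_one_side(model, g, t_tol = 1e-5,
                                         max_space = 2e6)), numeric(1))
  expect_true(all(diff(pv) < 0))
})

test_that("inactive clusters do not change the saddlepoint mid-p", {
  set.seed(27)
  ss <- random_score_set(M = 3, n = c(4, 4, 4))
  base <- as.numeric(dsa_midp(ss, "upper"))
  # append a w=0 cluster, a w=n cluster and a constant-score cluster
  cl2 <- c(ss$cluster, rep(4L, 2), rep(5L, 2), rep(6L, 3))
  w2 <- c(ss$w, 5, -2, 3, 1, 4, 4, 4)
  z2 <- c(ss$zeta, 0L, 0L, 1L, 1L, 1L, 0L, 0L)
  ss2 <- assemble_scores(cl2, w2, z2, center = FALSE)
  expect_equal(as.numeric(dsa_midp(ss2, "upper")), base, tolerance = 1e-8)
})

test_that("degenerate and boundary configurations follow the conventions", {
  con <- assemble_scores(rep(1:2, each = 2), rep(0, 4), c(1, 0, 1, 0),
                         center = FALSE)
  expect_error(dsa_midp(con), "degenerate")
  # observed statistic at the support maximum: mid-p = atom mass / 2
  ss <- assemble_scores(rep(1:2, each = 2), c(1, -1, 2, -2), c(1, 0, 1, 0),
                        center = FALSE)
  expect_equal(as.numeric(dsa_midp(ss, "upper")),
               as.numeric(exact_midp(ss, "upper")))  # = 0.125
  expect_equal(as.numeric(dsa_midp(ss, "upper")), 0.125)
  # and at the minimum
  ssmin <- assemble_scores(rep(1:2, each = 2), c(1, -1, 2, -2),
                           c(0, 1, 0, 1), center = FALSE)
  expect_equal(as.numeric(dsa_midp(ssmin, "upper")), 1 - 0.125)
})

test_that("small-tilt limit stays continuous and near the exact mid-p", {
  # an asymmetric instance evaluated exactly at its permutation mean
  ss <- assemble_scores(rep(1:3, each = 3), c(1, 2, 6, 1, 3, 8, 2, 2, 7),
                        c(1, 0, 0, 0, 1, 0, 1, 0, 0), center = TRUE)
  model <- cgf_model(ss)
  mean0 <- cgf_eval(model, 0, numeric(model$m))$K_t
  ss$zeta <- ss$zeta  # keep observed zeta; evaluate the internal path
  up <- saddlerank:::dsa_one_side(model, mean0, t_tol = 1e-5,
                                  max_space = 2e6)
  expect_true(attr(up, "diagnostics")$small_t)
  expect_gt(as.numeric(up), 0.35)
  expect_lt(as.numeric(up), 0.65)
  # continuity: a hair away from the mean gives nearly the same value
  up2 <- saddlerank:::dsa_one_side(model, mean0 + 1e-7, t_tol = 1e-5,
                                   max_space = 2e6)
  expect_lt(abs(as.numeric(up) - as.numeric(up2)), 1e-3)
})

test_that("saddlepoint tracks the exact mid-p closely away from tiny lattices", {
  set.seed(28)
  err <- replicate(40, {
    ss <- random_score_set(M = 5, n = sample(4:5, 5, replace = TRUE))
    abs(as.numeric(dsa_midp(ss, "upper")) -
        as.numeric(exact_midp(ss, "upper")))
  })
  expect_lt(median(err), 0.01)
  expect_lt(max(err), 0.06)
})
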