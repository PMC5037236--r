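fake_est <- function(theta, b, a, model = "2PL") {
  irt_estimates(theta, b, a, rep(0, length(theta)), rep(0, length(b)),
                rep(0, length(b)), "VB", "matched", model)
}

test_that("alignment is exact on identical and planted-transform inputs", {
  tp <- draw_parameters(50, 6, "2PL", seed = 301)
  est <- fake_est(tp$theta, tp$b, tp$a)
  al <- align_estimates(est, tp, "2PL")
  expect_equal(al$s, 1, tolerance = 1e-4)
  expect_equal(al$t, 0, tolerance = 1e-4)
  expect_lt(al$objective, 1e-6)
  # estimates produced on a shifted/scaled but equivalent solution
  s0 <- 2
  t0 <- 0.5
  est2 <- fake_est(s0 * tp$theta + t0, s0 * tp$b + t0, tp$a / s0)
  al2 <- align_estimates(est2, tp, "2PL")
  expect_equal(al2$s, 1 / s0, tolerance = 1e-3)
  expect_equal(al2$t, -t0 / s0, tolerance = 1e-3)
  expect_lt(al2$objective, 1e-6)
  expect_equal(al2$aligned$a, tp$a, tolerance = 1e-3)
})

test_that("1PL alignment optimizes the shift only", {
  tp <- draw_parameters(40, 5, "1PL", seed = 311)
  est <- fake_est(tp$theta - 0.8, tp$b - 0.8, tp$a, "1PL")
  al <- align_estimates(est, tp, "1PL")
  expect_identical(al$s, 1)
  expect_equal(al$t, 0.8, tolerance = 1e-5)
  expect_lt(al$objective, 1e-6)
})

test_that("the returned alignment beats a dense (s, t) grid", {
  set.seed(321)
  tp <- draw_parameters(30, 5, "2PL", seed = 322)
  est <- fake_est(1.3 * tp$theta + 0.2 + rnorm(30, 0, 0.3),
                  1.3 * tp$b + 0.2 + rnorm(5, 0, 0.2),
                  tp$a / 1.3 * exp(rnorm(5, 0, 0.1)))
  al <- align_estimates(est, tp, "2PL")
  grid_s <- seq(0.5, 2, length.out = 201)
  grid_t <- seq(-1, 1, length.out = 201)
  Jg <- outer(grid_s, grid_t, Vectorize(function(s, t) {
    irtlab:::align_objective(est, tp, s, t, TRUE)
  }))
  expect_lte(al$objective, min(Jg) + 1e-8)
})

test_that("degenerate truth skips alignment with a warning", {
  tp <- irt_parameters(rep(0, 4), rep(0, 3), rep(1, 3), "1PL")
  est <- fake_est(rnorm(4), rnorm(3), rep(1, 3), "1PL")
  expect_warning(al <- align_estimates(est, tp, "1PL"), "degenerate")
  expect_equal(c(al$s, al$t), c(1, 0))
})

test_that("average RMSE metrics follow their definitions", {
  tp <- draw_parameters(20, 4, "2PL", seed = 331)
  est <- fake_est(tp$theta, tp$b, tp$a)
  expect_equal(average_rmse_theta(list(est), list(tp)), 0)
  expect_equal(average_rmse_p(list(est), list(tp)), 0)
  # hand-computed: errors (3, 4) over two persons -> sqrt(25/2)
  tp2 <- irt_parameters(c(0, 0), c(0, 0.5), model = "1PL")
  est2 <- fake_est(c(3, 4), c(0, 0.5), c(1, 1), "1PL")
  expect_equal(average_rmse_theta(list(est2), list(tp2)),
               sqrt((9 + 16) / 2), tolerance = 1e-12)
  # two replications average their per-replication RMSEs
  expect_equal(average_rmse_theta(list(est2, est), list(tp2, tp)),
               sqrt(12.5) / 2, tolerance = 1e-12)
  expect_equal(average_rmse_b(list(est2), list(tp2)), 0)
  expect_error(average_rmse_theta(list(), list()), "nonempty")
})

test_that("average SE nests means over parameters then replications", {
  expect_equal(average_se(list(rep(0.2, 5))), 0.2)
  expect_equal(average_se(list(c(0.1, 0.3), c(0.2, 0.2))), 0.2)
  expect_equal(average_se(list(c(0, 0))), 0)
})

test_that("eta-squared decomposition matches hand computation", {
  # balanced 2x2 with R = 2: hand-decomposed sums of squares
  df <- expand.grid(EM = c("A", "B"), SS = c(250, 500), TL = 10,
                    rep = 1:2)
  df$value <- c(1, 3, 2, 6, 1, 3, 2, 6) # EM effect + EM:SS pattern
  out <- anova_eta2(df)
  gm <- mean(df$value)
  ss_em <- 8 / 2 * sum((tapply(df$value, df$EM, mean) - gm)^2) * 1
  expect_equal(out$ss[out$effect == "EM"],
               4 * sum((tapply(df$value, df$EM, mean) - gm)^2),
               tolerance = 1e-10)
  expect_equal(sum(out$eta2_pct), 100, tolerance = 1e-9)
  # identical metric everywhere: no variance to attribute
  df0 <- df
  df0$value <- 5
  out0 <- anova_eta2(df0)
  expect_true(all(out0$eta2_pct[out0$effect != "Residuals"] == 0))
  # one-factor toy, all variance between levels
  df1 <- data.frame(EM = c("A", "A", "B", "B"), SS = 1, TL = 1,
                    value = c(0, 0, 1, 1))
  out1 <- anova_eta2(df1)
  expect_equal(out1$eta2_pct[out1$effect == "EM"], 100)
  expect_identical(out1$size[out1$effect == "EM"], "large")
  # unbalanced designs are refused
  expect_error(anova_eta2(df[-1, ]), "unbalanced")
})
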