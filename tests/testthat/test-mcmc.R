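test_that("conjugate hyperparameter draws match the closed-form posterior", {
  set.seed(91)
  th <- rnorm(40, 1.3, 0.8)
  u <- 1.7
  # m | th, u ~ N( S u mean(th) / (S u + 1e-6), 1 / (S u + 1e-6) )
  prec <- 40 * u + 1e-6
  mu <- u * sum(th) / prec
  dr <- irtlab:::.conj_mean_draws_cpp(th, u, 1e6, 4e4)
  expect_lt(abs(mean(dr) - mu), 4 / sqrt(prec) / sqrt(4e4) * 1.5 + 1e-4)
  expect_equal(sd(dr), 1 / sqrt(prec), tolerance = 0.03)
  # u | th, m ~ Gamma(1 + S/2, 1 + sum((th - m)^2) / 2)
  m <- 1.1
  shape <- 1 + 20
  rate <- 1 + sum((th - m)^2) / 2
  du <- irtlab:::.conj_prec_draws_cpp(th, m, 1, 1, 4e4)
  expect_equal(mean(du), shape / rate, tolerance = 0.02)
  expect_equal(var(du), shape / rate^2, tolerance = 0.05)
})

test_that("posterior means and SDs match dense quadrature on tiny data", {
  # two-item instances under matched and standard-vague regimes; the vague
  # case uses a few more persons so the likelihood (not the variance-1000
  # prior tail) determines where the difficulty posterior lives
  set.seed(200)
  Ysmall <- matrix(c(1L, 0L, 1L, 1L), 2, 2)
  Ybig <- rbind(Ysmall, matrix(as.integer(runif(20) < 0.5), 10, 2))
  cases <- list(list(regime = "matched", Y = Ysmall, brange = c(-12, 12)),
                list(regime = "stdvague", Y = Ybig, brange = c(-15, 15)))
  for (cs in cases) {
    pr <- make_prior(cs$regime, "1PL")
    ex <- quad_posterior(cs$Y, theta_var = unname(pr$theta["var"]),
                         b_var = unname(pr$b["var"]),
                         n_t = 241, n_b = 301, b_range = cs$brange)
    dr <- fit_mcmc(cs$Y, "1PL", pr, chains = 1, burnin = 3000, keep = 12000,
                   seed = 12)
    sm <- summarize_chains(dr)
    for (i in 1:2) {
      se <- mcse_batch(dr$theta[[1]][, i])
      expect_lt(abs(sm$theta[i] - ex$E_theta[i]), 3 * se + 0.02)
      expect_lt(abs(sm$se_theta[i] - ex$SD_theta[i]), 0.05)
    }
    for (k in 1:2) {
      se <- mcse_batch(dr$b[[1]][, k])
      expect_lt(abs(sm$b[k] - ex$E_b[k]), 3 * se + 0.03)
      expect_lt(abs(sm$se_b[k] - ex$SD_b[k]), 0.1 * ex$SD_b[k] + 0.05)
    }
  }
})

test_that("single-cell posterior mean matches 2-D quadrature", {
  Y <- matrix(1L, 1, 1)
  ex <- quad_posterior(Y)
  dr <- fit_mcmc(Y, "1PL", make_prior("matched", "1PL"), chains = 1,
                 burnin = 2000, keep = 10000, seed = 3)
  sm <- summarize_chains(dr)
  se <- mcse_batch(dr$theta[[1]][, 1])
  expect_lt(abs(sm$theta[1] - ex$E_theta[1]), 3 * se + 0.01)
})

test_that("hierarchical priors inflate difficulty posterior SDs", {
  dat <- make_1pl_data(150, 8, seed = 101)
  hi <- summarize_chains(fit_mcmc(dat$Y, "1PL",
                                  make_prior("hierarchical", "1PL"),
                                  burnin = 2000, keep = 1000, seed = 7))
  ma <- summarize_chains(fit_mcmc(dat$Y, "1PL", make_prior("matched", "1PL"),
                                  burnin = 2000, keep = 1000, seed = 7))
  expect_gt(mean(hi$se_b), mean(ma$se_b))
})

test_that("shift-invariant contrasts agree between regimes on tiny data", {
  # the hierarchical shift is unidentified; contrasts such as b2 - b1 are
  # identified and should sit near the (proper-prior) quadrature values of
  # the matched regime's contrast when the data dominate
  Y <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 0L), c(1L, 0L))
  dr <- fit_mcmc(Y, "1PL", make_prior("hierarchical", "1PL"), chains = 1,
                 burnin = 4000, keep = 8000, seed = 31)
  contrast <- dr$b[[1]][, 2] - dr$b[[1]][, 1]
  expect_lt(abs(mean(dr$theta[[1]][, 2] - dr$theta[[1]][, 1]) -
                  mean(dr$theta[[1]][, 2]) +
                  mean(dr$theta[[1]][, 1])), 1e-10) # arithmetic identity
  expect_gt(mean(contrast), 0) # item 2 harder: fewer correct answers
  expect_true(is.finite(sd(contrast)))
})

test_that("summaries pool chains with the n-1 SD convention", {
  dat <- make_1pl_data(30, 4, seed = 111)
  dr <- fit_mcmc(dat$Y, "1PL", make_prior("matched", "1PL"), chains = 2,
                 burnin = 200, keep = 50, seed = 1)
  sm <- summarize_chains(dr)
  pooled <- rbind(dr$theta[[1]], dr$theta[[2]])
  expect_equal(sm$theta, colMeans(pooled))
  expect_equal(sm$se_theta, apply(pooled, 2, sd))
  # two-point sanity: mean 1, sd with n-1 divisor
  x <- c(0, 2)
  expect_equal(mean(x), 1)
  expect_equal(sd(x), sqrt(2))
})

test_that("PSRF separates mixed from unmixed chains", {
  dat <- make_1pl_data(40, 4, seed = 121)
  dr <- fit_mcmc(dat$Y, "1PL", make_prior("matched", "1PL"), chains = 3,
                 burnin = 1500, keep = 1500, seed = 5)
  ps <- psrf(dr, "b", 2)
  expect_lt(ps$point, 1.05)
  expect_gte(ps$upper, ps$point)
  expect_lt(mpsrf(dr), 1.1)
  # cross-check the native point estimate against coda on mixed chains
  gd <- coda::gelman.diag(coda::mcmc.list(lapply(dr$b, function(m) {
    coda::mcmc(m[, 2])
  })), autoburnin = FALSE)
  expect_equal(ps$point, unname(gd$psrf[1, 1]), tolerance = 0.02)
  # identical chains: corrected PSRF equals sqrt((n-1)/n) <= 1
  dr2 <- dr
  dr2$b <- list(dr$b[[1]], dr$b[[1]])
  dr2$chains <- 2
  ps2 <- psrf(dr2, "b", 1)
  expect_lt(abs(ps2$point - 1), 1e-3)
  expect_lte(ps2$point, 1)
  # grossly separated chains
  dr3 <- dr2
  dr3$b <- list(dr$b[[1]], dr$b[[1]] + 10)
  ps3 <- psrf(dr3, "b", 1)
  expect_gt(ps3$point, 1.2)
  expect_error(psrf(fit_mcmc(dat$Y, "1PL", make_prior("matched", "1PL"),
                             chains = 1, burnin = 100, keep = 100, seed = 2),
                    "b", 1), "two chains")
})

test_that("the half-width test behaves on iid, trending, constant chains", {
  set.seed(131)
  iid <- rnorm(5000, mean = 10, sd = 1)
  expect_true(halfwidth_test(iid)$pass)
  # a drifting chain must not pass overall; a moderate drift relative to
  # the noise is caught by the stationarity stage itself
  strong <- seq(0, 20, length.out = 2000) + rnorm(2000, 0, 0.3)
  expect_false(halfwidth_test(strong)$pass)
  gentle <- seq(0, 5, length.out = 2000) + rnorm(2000, 0, 1)
  expect_false(halfwidth_test(gentle)$stationarity)
  expect_true(halfwidth_test(rep(2.5, 500))$pass)
  expect_error(halfwidth_test(rnorm(50)), "too short")
})

test_that("runs are reproducible in the seed", {
  dat <- make_1pl_data(25, 4, seed = 141)
  d1 <- fit_mcmc(dat$Y, "1PL", make_prior("matched", "1PL"), burnin = 100,
                 keep = 50, seed = 9)
  d2 <- fit_mcmc(dat$Y, "1PL", make_prior("matched", "1PL"), burnin = 100,
                 keep = 50, seed = 9)
  expect_identical(d1$theta, d2$theta)
  expect_identical(d1$b, d2$b)
})

test_that("chain draws persist as long-format CSV", {
  dat <- make_1pl_data(20, 3, seed = 151)
  dr <- fit_mcmc(dat$Y, "1PL", make_prior("hierarchical", "1PL"),
                 chains = 2, burnin = 50, keep = 20, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_chains(dr, f)
  df <- read.csv(f)
  expect_setequal(names(df), c("iteration", "chain", "parameter", "value"))
  # 2 chains x 20 draws x (20 theta + 3 b + 4 hypers)
  expect_identical(nrow(df), 2L * 20L * 27L)
  back <- df$value[df$parameter == "b[2]" & df$chain == 1]
  expect_equal(back, dr$b[[1]][, 2])
  unlink(f)
})
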