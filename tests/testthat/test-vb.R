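test_that("the Saul-Jordan bound has its closed-form values and limits", {
  # v = 0 collapses to log(1 + e^m) for any xi
  expect_equal(sj_bound(0, 0, 0.3), log(2), tolerance = 1e-12)
  expect_equal(sj_bound(2.5, 0, 0.77), log1p(exp(2.5)), tolerance = 1e-12)
  expect_equal(sj_bound(0, 1, 0.5), log(2) + 1 / 8, tolerance = 1e-12)
  expect_error(sj_bound(0, -1, 0.5), "nonnegative")
  expect_error(sj_bound(0, 1, 1), "inside")
})

test_that("the bound dominates the Gauss-Hermite truth everywhere", {
  set.seed(201)
  for (rep in 1:60) {
    m <- runif(1, -6, 6)
    v <- runif(1, 0, 9)
    xi <- runif(1, 0.02, 0.98)
    truth <- softplus_gh(m, v)
    expect_gte(sj_bound(m, v, xi) - truth, -1e-10)
  }
  # and is tight at v = 0
  expect_equal(sj_bound(1.3, 0, 0.4), softplus_gh(1.3, 0), tolerance = 1e-9)
})

test_that("sj_optimal_xi minimizes the bound", {
  expect_equal(sj_optimal_xi(0, 0.7), 0.5, tolerance = 1e-9)
  expect_equal(sj_optimal_xi(0, 4), 0.5, tolerance = 1e-9)
  expect_gt(sj_optimal_xi(30, 2), 0.999)
  expect_lt(sj_optimal_xi(-30, 2), 0.001)
  # grid argmin oracle at (1, 2)
  xg <- seq(1e-5, 1 - 1e-5, by = 1e-5)
  vals <- sj_bound(1, 2, xg)
  expect_lt(abs(sj_optimal_xi(1, 2) - xg[which.min(vals)]), 1e-4)
  # stationarity condition
  xi <- sj_optimal_xi(1, 2)
  expect_equal(xi, plogis(1 + (1 - 2 * xi) * 2 / 2), tolerance = 1e-9)
})

test_that("the variational objective ascends monotonically and audits", {
  dat <- make_1pl_data(60, 6, seed = 211)
  for (regime in c("matched", "stdvague", "hierarchical")) {
    fit <- fit_vb(dat$Y, "1PL", make_prior(regime, "1PL"), tol = 1e-8,
                  max_sweeps = 400)
    expect_true(all(diff(fit$state$bound_trace) > -1e-8))
    expect_equal(vb_bound_value(fit$state, dat$Y,
                                make_prior(regime, "1PL")),
                 fit$state$bound, tolerance = 1e-6)
  }
  tp <- draw_parameters(60, 5, "2PL", seed = 212)
  Y2 <- simulate_responses(tp, seed = 213)
  fit2 <- fit_vb(Y2, "2PL", make_prior("matched", "2PL"), tol = 1e-8)
  expect_true(all(diff(fit2$state$bound_trace) > -1e-8))
  expect_equal(vb_bound_value(fit2$state, Y2, make_prior("matched", "2PL")),
               fit2$state$bound, tolerance = 1e-6)
})

test_that("perturbing a converged factor can only lower the objective", {
  dat <- make_1pl_data(40, 4, seed = 221)
  fit <- fit_vb(dat$Y, "1PL", make_prior("matched", "1PL"), tol = 1e-10,
                max_sweeps = 2000)
  st <- fit$state
  f0 <- vb_bound_value(st, dat$Y)
  for (delta in c(-0.05, 0.05)) {
    s2 <- st
    s2$mu_t[3] <- s2$mu_t[3] + delta
    expect_lt(vb_bound_value(s2, dat$Y), f0 + 1e-9)
    s3 <- st
    s3$mu_b[2] <- s3$mu_b[2] + delta
    expect_lt(vb_bound_value(s3, dat$Y), f0 + 1e-9)
  }
})

test_that("swapping identical items yields identical factors", {
  set.seed(231)
  th <- rnorm(70)
  col <- as.integer(runif(70) < plogis(th - 0.3))
  col[1:2] <- c(0L, 1L)
  oth <- as.integer(runif(70) < plogis(th + 0.6))
  oth[3:4] <- c(0L, 1L)
  Y <- cbind(col, col, oth)
  fit <- fit_vb(Y, "1PL", make_prior("matched", "1PL"), tol = 1e-9)
  expect_equal(fit$state$mu_b[1], fit$state$mu_b[2], tolerance = 1e-6)
  expect_equal(fit$state$v_b[1], fit$state$v_b[2], tolerance = 1e-6)
})

test_that("objective stays below the true log marginal likelihood", {
  # 1PL instances where dense quadrature gives the exact marginal
  set.seed(241)
  for (case in 1:3) {
    S <- sample(2:3, 1)
    Y <- matrix(as.integer(runif(S * 2) < 0.5), S, 2)
    for (regime in c("matched", "stdvague")) {
      pr <- make_prior(regime, "1PL")
      ex <- quad_posterior(Y, theta_var = unname(pr$theta["var"]),
                           b_var = unname(pr$b["var"]), n_t = 241,
                           n_b = 401, b_range = c(-60, 60))
      fit <- fit_vb(Y, "1PL", pr, tol = 1e-9, max_sweeps = 1000)
      expect_lt(fit$state$bound, ex$logZ + 1e-6)
    }
  }
})

test_that("tiny-instance posterior means match dense quadrature", {
  Y <- matrix(1L, 1, 1)
  fit <- fit_vb(Y, "1PL", make_prior("matched", "1PL"), tol = 1e-10)
  ex <- quad_posterior(Y)
  expect_lt(abs(fit$state$mu_t[1] - ex$E_theta[1]), 0.05)
  expect_lt(abs(fit$state$mu_b[1] - ex$E_b[1]), 0.05)
  # mixed instance, both fixed regimes
  set.seed(251)
  Y2 <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L))
  for (regime in c("matched", "stdvague")) {
    pr <- make_prior(regime, "1PL")
    ex2 <- quad_posterior(Y2, theta_var = unname(pr$theta["var"]),
                          b_var = unname(pr$b["var"]), n_t = 241,
                          n_b = 401, b_range = c(-40, 40))
    fit2 <- fit_vb(Y2, "1PL", pr, tol = 1e-10, max_sweeps = 1000)
    expect_lt(max(abs(fit2$state$mu_t - ex2$E_theta)), 0.12)
    expect_lt(max(abs(fit2$state$mu_b - ex2$E_b)), 0.25)
  }
})

test_that("hierarchical conjugate factor updates have the derived form", {
  dat <- make_1pl_data(80, 6, seed = 261)
  fit <- fit_vb(dat$Y, "1PL", make_prior("hierarchical", "1PL"), tol = 1e-8)
  st <- fit$state
  expect_equal(st$hyper$t$Au, 1 + 80 / 2)
  expect_equal(st$hyper$b$Au, 1 + 6 / 2)
  # rate = 1 + E_q[sum (theta_i - m_theta)^2] / 2 at the current factors
  rate_t <- 1 + 0.5 * (sum((st$mu_t - st$hyper$t$Mm)^2) + sum(st$v_t) +
                         80 * st$hyper$t$Vm)
  expect_equal(st$hyper$b$Bu,
               1 + 0.5 * (sum((st$mu_b - st$hyper$b$Mm)^2) + sum(st$v_b) +
                            6 * st$hyper$b$Vm), tolerance = 1e-8)
  expect_equal(st$hyper$t$Bu, rate_t, tolerance = 1e-8)
  # hierarchical 1PL carries 8 extra free hyper-factor parameters
  expect_length(unlist(st$hyper[c("t", "b")]), 8)
})

test_that("VB discriminations use the lognormal mean and SD", {
  tp <- draw_parameters(120, 4, "2PL", seed = 271)
  Y <- simulate_responses(tp, seed = 272)
  fit <- fit_vb(Y, "2PL", make_prior("matched", "2PL"), tol = 1e-8)
  st <- fit$state
  expect_equal(fit$estimates$a, exp(st$mu_z + st$v_z / 2))
  expect_equal(fit$estimates$se_a,
               sqrt((exp(st$v_z) - 1) * exp(2 * st$mu_z + st$v_z)))
  expect_true(all(fit$estimates$a > 0))
  expect_true(all(st$xi > 0 & st$xi < 1))
})

test_that("non-convergence is flagged, not thrown", {
  dat <- make_1pl_data(50, 5, seed = 281)
  fit <- fit_vb(dat$Y, "1PL", make_prior("matched", "1PL"), tol = 0,
                max_sweeps = 3)
  expect_false(fit$converged)
  expect_false(fit$estimates$details$converged)
})
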