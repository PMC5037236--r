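#' Saul-Jordan upper bound on the softplus moment of a Gaussian
#'
#' For `Z ~ N(m, v)` and a variational parameter `xi` in (0, 1):
#' `SJ(m, v, xi) = xi m + log(exp(-xi m + xi^2 v / 2) +
#' exp((1 - xi) m + (1 - xi)^2 v / 2))`, evaluated through log-sum-exp.
#' At `v = 0` the bound collapses to `log(1 + e^m)` exactly, for any `xi`.
#' Arguments recycle.
#'
#' @param m mean of the Gaussian logit.
#' @param v nonnegative variance of the Gaussian logit.
#' @param xi variational parameter strictly inside (0, 1).
#' @return The bound value.
#' @examples
#' sj_bound(0, 0, 0.3) # log(2)
#' sj_bound(0, 1, 0.5) # log(2) + 1/8
#' @export
sj_bound <- function(m, v, xi) {
  if (any(v < 0)) stop("variance must be nonnegative")
  if (any(xi <= 0 | xi >= 1)) stop("xi must lie strictly inside (0, 1)")
  A <- -xi * m + 0.5 * xi^2 * v
  B <- (1 - xi) * m + 0.5 * (1 - xi)^2 * v
  xi * m + pmax(A, B) + log1p(exp(-abs(A - B)))
}

#' Optimal Saul-Jordan variational parameter
#'
#' Returns the unique `xi` in (0, 1) minimizing [sj_bound] in `xi`, i.e. the
#' solution of the stationarity condition
#' `xi = plogis(m + (1 - 2 xi) v / 2)`, found by safeguarded Newton
#' iteration on the monotone residual. Arguments recycle.
#'
#' @param m mean of the Gaussian logit.
#' @param v nonnegative variance.
#' @return The minimizing `xi`.
#' @examples
#' sj_optimal_xi(0, 3) # 0.5 by symmetry
#' @export
sj_optimal_xi <- function(m, v) {
  if (any(v < 0)) stop("variance must be nonnegative")
  n <- max(length(m), length(v))
  m <- rep_len(as.numeric(m), n)
  v <- rep_len(as.numeric(v), n)
  out <- .sj_xi_solve_cpp(matrix(m, 1), matrix(v, 1),
                          matrix(0.5, 1, n), 60L, 1e-12)
  drop(out)
}

rep_row <- function(x, S) matrix(x, S, length(x), byrow = TRUE)

# first two moments of the logit eta = a (theta - b) under the factorized
# posterior; exact for the 1PL, moment-matched Gaussian for the 2PL using
# the lognormal moments of a = exp(z)
vb_moments <- function(st) {
  if (st$model == "1PL") {
    list(m = outer(st$mu_t, st$mu_b, "-"),
         v = outer(st$v_t, st$v_b, "+"))
  } else {
    S <- length(st$mu_t)
    alpha <- exp(st$mu_z + st$v_z / 2)
    A2 <- exp(2 * st$mu_z + 2 * st$v_z)
    aR <- rep_row(alpha, S)
    A2R <- rep_row(A2, S)
    d <- outer(st$mu_t, st$mu_b, "-")
    Td <- d^2 + outer(st$v_t, st$v_b, "+")
    list(m = d * aR, v = A2R * Td - aR^2 * d^2,
         aR = aR, A2R = A2R, d = d, Td = Td)
  }
}

# prior mean / precision seen by one factor block ("t", "b", "z")
vb_block_prior <- function(st, block) {
  if (st$regime == "hierarchical") {
    h <- st$hyper[[block]]
    list(pm = h$Mm, pe = h$Au / h$Bu, extra_var = h$Vm)
  } else {
    p <- st$fixed[[block]]
    list(pm = p[1], pe = 1 / p[2], extra_var = 0)
  }
}

# local objective pieces: bound terms varying with one block's (mu, v)
vb_local_rows <- function(ev_row, mu, v, pr) {
  ev_row - pr$pe * ((mu - pr$pm)^2 + v) / 2 + 0.5 * log(v)
}

vb_eval <- function(st, Y, derivs = TRUE) {
  mom <- vb_moments(st)
  ev <- .sj_eval_cpp(mom$m, mom$v, st$xi, Y, derivs)
  list(mom = mom, ev = ev)
}

vb_stats <- function(st, Y) {
  .vb_stats_cpp(st$mu_t, st$v_t, st$mu_b, st$v_b,
                st$mu_z %||% numeric(0), st$v_z %||% numeric(0),
                st$xi, Y, model_code(st$model))
}

# joint guarded update of one block's Gaussian means and variances: a Newton
# step on the means plus the stationary-point update of the variances, both
# derived from the same single-pass sufficient statistics, accepted
# coordinate-wise only where the block's local objective does not decrease.
# Returns the updated state with the statistics at the accepted point.
vb_update_block <- function(st, Y, block, stats) {
  pr <- vb_block_prior(st, block)
  if (block == "t") {
    mu <- st$mu_t; vv <- st$v_t
    grad <- stats$gt - pr$pe * (mu - pr$pm)
    curv <- stats$ct + pr$pe
    vtarget <- 1 / (pr$pe + 2 * stats$stt)
    f0 <- vb_local_rows(stats$row, mu, vv, pr)
  } else if (block == "b") {
    mu <- st$mu_b; vv <- st$v_b
    grad <- stats$gb - pr$pe * (mu - pr$pm)
    curv <- stats$cb + pr$pe
    vtarget <- 1 / (pr$pe + 2 * stats$sbb)
    f0 <- vb_local_rows(stats$col, mu, vv, pr)
  } else { # z: Newton in the mean, guarded log-variance step
    mu <- st$mu_z; vv <- st$v_z
    grad <- stats$gz - pr$pe * (mu - pr$pm)
    curv <- stats$cz + pr$pe
    gv <- stats$gvz - pr$pe / 2 + 1 / (2 * vv)
    hx <- stats$hvz + 0.5
    vtarget <- vv * exp(pmax(pmin(gv * vv / hx, 1), -1))
    f0 <- vb_local_rows(stats$col, mu, vv, pr)
  }
  step <- pmax(pmin(grad / curv, 3), -3)
  lstep <- log(vtarget / vv)
  lambda <- rep(1, length(mu))
  for (try in 1:7) {
    cand_mu <- mu + lambda * step
    cand_v <- vv * exp(lambda * lstep)
    st2 <- st
    if (block == "t") {
      st2$mu_t <- cand_mu; st2$v_t <- cand_v
    } else if (block == "b") {
      st2$mu_b <- cand_mu; st2$v_b <- cand_v
    } else {
      st2$mu_z <- cand_mu; st2$v_z <- cand_v
    }
    stats2 <- vb_stats(st2, Y)
    fside <- if (block == "t") stats2$row else stats2$col
    f1 <- vb_local_rows(fside, cand_mu, cand_v, pr)
    worse <- f1 < f0 - 1e-10
    if (!any(worse)) break
    lambda[worse] <- if (try < 6) lambda[worse] / 2 else 0
  }
  list(st = st2, stats = stats2)
}

# exact conjugate coordinate updates of the hierarchical hyper-factors
vb_update_hypers <- function(st) {
  hv <- st$hyper_mean_var
  s0 <- st$hyper_prec_shape
  r0 <- st$hyper_prec_rate
  upd <- function(h, mu, v) {
    n <- length(mu)
    Eu <- h$Au / h$Bu
    prec <- n * Eu + 1 / hv
    h$Mm <- Eu * sum(mu) / prec
    h$Vm <- 1 / prec
    h$Au <- s0 + n / 2
    h$Bu <- r0 + 0.5 * (sum((mu - h$Mm)^2) + sum(v) + n * h$Vm)
    h
  }
  st$hyper$t <- upd(st$hyper$t, st$mu_t, st$v_t)
  st$hyper$b <- upd(st$hyper$b, st$mu_b, st$v_b)
  if (st$model == "2PL") {
    st$hyper$z <- upd(st$hyper$z, st$mu_z, st$v_z)
  }
  st
}

# prior cross-entropy + entropy part of the objective (everything except
# the likelihood bound, which is invariant under the equivalence transforms)
vb_prior_part <- function(st) {
  gauss_block <- function(mu, v, block) {
    n <- length(mu)
    if (st$regime == "hierarchical") {
      h <- st$hyper[[block]]
      Eu <- h$Au / h$Bu
      Elogu <- digamma(h$Au) - log(h$Bu)
      cross <- 0.5 * n * (Elogu - log(2 * pi)) -
        0.5 * Eu * sum((mu - h$Mm)^2 + v + h$Vm)
      ent <- 0.5 * sum(log(2 * pi * exp(1) * v))
      cross + ent
    } else {
      p <- st$fixed[[block]]
      sum(0.5 + 0.5 * log(v / p[2]) - ((mu - p[1])^2 + v) / (2 * p[2]))
    }
  }
  val <- gauss_block(st$mu_t, st$v_t, "t") +
    gauss_block(st$mu_b, st$v_b, "b")
  if (st$model == "2PL") val <- val + gauss_block(st$mu_z, st$v_z, "z")
  if (st$regime == "hierarchical") {
    hv <- st$hyper_mean_var
    s0 <- st$hyper_prec_shape
    r0 <- st$hyper_prec_rate
    hyper_block <- function(h) {
      mterm <- 0.5 + 0.5 * log(h$Vm / hv) - (h$Mm^2 + h$Vm) / (2 * hv)
      Eu <- h$Au / h$Bu
      Elogu <- digamma(h$Au) - log(h$Bu)
      elogp <- s0 * log(r0) - lgamma(s0) + (s0 - 1) * Elogu - r0 * Eu
      ent <- h$Au - log(h$Bu) + lgamma(h$Au) + (1 - h$Au) * digamma(h$Au)
      mterm + elogp + ent
    }
    val <- val + hyper_block(st$hyper$t) + hyper_block(st$hyper$b)
    if (st$model == "2PL") val <- val + hyper_block(st$hyper$z)
  }
  val
}

# full variational objective recomputed from scratch
vb_bound_state <- function(st, Y) {
  e <- vb_eval(st, Y, derivs = FALSE)
  sum(e$ev$row) + vb_prior_part(st)
}

# apply the likelihood-equivalent reparameterization theta -> c theta + d,
# b -> c b + d, a -> a / c (log a -> log a - log c) to the factor means and
# variances (hierarchical hyper-factors co-transform); the logit moments
# (m, v) and hence the likelihood part of the bound are unchanged
vb_apply_mode <- function(st, logc, d) {
  cc <- exp(logc)
  st$mu_t <- cc * st$mu_t + d
  st$v_t <- cc^2 * st$v_t
  st$mu_b <- cc * st$mu_b + d
  st$v_b <- cc^2 * st$v_b
  if (st$model == "2PL") st$mu_z <- st$mu_z - logc
  if (st$regime == "hierarchical") {
    for (blk in c("t", "b")) {
      st$hyper[[blk]]$Mm <- cc * st$hyper[[blk]]$Mm + d
      st$hyper[[blk]]$Vm <- cc^2 * st$hyper[[blk]]$Vm
      st$hyper[[blk]]$Bu <- cc^2 * st$hyper[[blk]]$Bu
    }
    if (st$model == "2PL") st$hyper$z$Mm <- st$hyper$z$Mm - logc
  }
  st
}

# one-dimensional (1PL) or two-dimensional (2PL) exact line search along the
# shift/scale equivalence modes: cheap (no likelihood evaluation) and a pure
# ascent step, it removes the slow drift coordinate ascent would otherwise
# exhibit along these weakly identified directions
vb_mode_jump <- function(st) {
  f0 <- vb_prior_part(st)
  if (st$model == "2PL") {
    o <- optim(c(0, 0), function(p) -vb_prior_part(vb_apply_mode(st, p[1],
                                                                 p[2])),
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 200))
    if (-o$value > f0) st <- vb_apply_mode(st, o$par[1], o$par[2])
  } else {
    o <- optimize(function(d) vb_prior_part(vb_apply_mode(st, 0, d)),
                  interval = c(-4, 4), maximum = TRUE, tol = 1e-10)
    if (o$objective > f0) st <- vb_apply_mode(st, 0, o$maximum)
  }
  st
}

#' Mean-field variational Bayes for 1PL/2PL models
#'
#' Coordinate ascent on a fully factorized Gaussian approximation of the
#' joint posterior: one Gaussian factor per ability, per difficulty, and
#' (2PL) per log-discrimination, plus Gaussian/Gamma factors for the
#' hierarchical population means and precisions. The intractable logistic
#' expectations are replaced by the Saul-Jordan bound with one variational
#' parameter `xi` per response, re-tightened at every sweep; for the 2PL the
#' non-Gaussian logit `a (theta - b)` is moment-matched to a Gaussian
#' before the bound is applied (exact for the 1PL). Each sweep updates xi,
#' then the ability, difficulty, and discrimination blocks by guarded Newton
#' steps on (mean, variance), then the hierarchical hyper-factors in closed
#' conjugate form; the objective is non-decreasing across sweeps.
#'
#' Point estimates are the factor means (discrimination reported as the
#' lognormal mean `exp(mu + v/2)`), standard errors the factor standard
#' deviations (lognormal SD for the discrimination).
#'
#' @param data S x L binary response matrix.
#' @param model `"1PL"` or `"2PL"`.
#' @param prior a prior object from [make_prior()] with regime other than `"none"`.
#' @param tol stop when the objective improves by less than this between
#'   sweeps.
#' @param max_sweeps sweep cap; hitting it sets `converged = FALSE` (with a
#'   warning flag, not an error).
#' @return A list of class `vb_fit`: `state` (factor parameters, xi, bound
#'   trace), `estimates` (an [irt_estimates]), `converged`, `sweeps`.
#' @export
fit_vb <- function(data, model = c("1PL", "2PL"), prior,
                   tol = 1e-6, max_sweeps = 500) {
  model <- match.arg(model)
  stopifnot(inherits(prior, "irt_prior"))
  if (prior$regime == "none") stop("VB requires a proper prior regime")
  Y <- as_response_matrix(data)
  check_binary_matrix(Y)
  S <- nrow(Y)
  L <- ncol(Y)

  st <- list(model = model, regime = prior$regime,
             mu_t = numeric(S), v_t = rep(1, S),
             mu_b = numeric(L), v_b = rep(1, L),
             xi = matrix(0.5, S, L))
  if (model == "2PL") {
    st$mu_z <- numeric(L)
    st$v_z <- rep(1, L)
  }
  if (prior$regime == "hierarchical") {
    st$hyper_mean_var <- unname(prior$hyper_mean["var"])
    st$hyper_prec_shape <- unname(prior$hyper_prec["shape"])
    st$hyper_prec_rate <- unname(prior$hyper_prec["rate"])
    h0 <- list(Mm = 0, Vm = 1, Au = 1, Bu = 1)
    st$hyper <- list(t = h0, b = h0, z = if (model == "2PL") h0)
  } else {
    st$fixed <- list(t = unname(prior$theta), b = unname(prior$b),
                     z = if (model == "2PL") unname(prior$loga))
  }

  trace <- numeric(0)
  f_prev <- -Inf
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    st$xi <- .vb_xi_cpp(st$mu_t, st$v_t, st$mu_b, st$v_b,
                        st$mu_z %||% numeric(0), st$v_z %||% numeric(0),
                        st$xi, model_code(model), 25L, 1e-11)
    stats <- vb_stats(st, Y)
    for (block in c("t", "b", if (model == "2PL") "z")) {
      up <- vb_update_block(st, Y, block, stats)
      st <- up$st; stats <- up$stats
    }
    if (prior$regime == "hierarchical") st <- vb_update_hypers(st)
    st <- vb_mode_jump(st)
    # likelihood part of the bound is unchanged by the hyper updates and the
    # mode jump, so the last block statistics still apply
    f <- sum(stats$row) + vb_prior_part(st)
    trace <- c(trace, f)
    if (f - f_prev < tol && sweep > 1) {
      converged <- TRUE
      break
    }
    f_prev <- f
  }
  st$bound <- trace[length(trace)]
  st$bound_trace <- trace
  class(st) <- "vb_state"

  if (model == "2PL") {
    a <- exp(st$mu_z + st$v_z / 2)
    se_a <- sqrt((exp(st$v_z) - 1) * exp(2 * st$mu_z + st$v_z))
  } else {
    a <- rep(1, L)
    se_a <- rep(0, L)
  }
  est <- irt_estimates(theta = st$mu_t, b = st$mu_b, a = a,
                       se_theta = sqrt(st$v_t), se_b = sqrt(st$v_b),
                       se_a = se_a,
                       method = "VB", prior = prior$regime, model = model,
                       details = list(sweeps = sweep, converged = converged,
                                      bound = st$bound))
  structure(list(state = st, estimates = est, converged = converged,
                 sweeps = sweep), class = "vb_fit")
}

#' @export
print.vb_fit <- function(x, ...) {
  cat(sprintf("vb_fit: %s, %s prior, %d sweeps, bound %.4f, converged: %s\n",
              x$estimates$model, x$estimates$prior, x$sweeps,
              x$state$bound, x$converged))
  invisible(x)
}

#' Recompute the variational objective of a VB state from scratch
#'
#' Audit companion to [fit_vb]: evaluates the full Saul-Jordan objective
#' (likelihood bound, prior cross-entropies, factor entropies) for an
#' arbitrary state; after a fit it matches the tracked bound.
#'
#' @param state a `vb_state` (or the `state` element of a `vb_fit`).
#' @param data the response matrix the state was fitted to.
#' @param prior the prior used (consistency-checked against the state).
#' @return The objective value (scalar).
#' @export
vb_bound_value <- function(state, data, prior) {
  stopifnot(inherits(state, "vb_state"))
  if (!missing(prior) && !is.null(prior$regime) &&
      prior$regime != state$regime) {
    stop("prior regime does not match the state")
  }
  vb_bound_state(state, as_response_matrix(data))
}
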