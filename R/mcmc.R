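#' Metropolis-within-Gibbs sampling for 1PL/2PL models
#'
#' Latent abilities, difficulties, and (for the 2PL) log-discriminations are
#' updated one at a time by Gaussian random-walk Metropolis steps against
#' their full conditionals (response likelihood times prior); under the
#' hierarchical regime the population means and precisions are updated by
#' exact conjugate Gibbs draws. Proposal standard deviations are adapted
#' during burn-in only (windows of 50 iterations, targeting acceptance rates
#' of 0.3-0.5), which leaves the retained chain a valid Markov chain.
#' Initial values: all latent parameters 0; hierarchical means 0 and
#' standard deviations 1. Discriminations are sampled on the log scale,
#' where the lognormal prior is normal.
#'
#' @param data S x L binary response matrix.
#' @param model `"1PL"` or `"2PL"`.
#' @param prior a prior object from [make_prior()] with regime other than `"none"`.
#' @param chains number of independent chains (>= 1).
#' @param burnin discarded iterations per chain (default 5000).
#' @param keep retained iterations per chain (default 1000).
#' @param seed integer seed; per-chain seeds are derived deterministically.
#' @return An object of class `irt_chains` with per-chain draw matrices
#'   (`theta`, `b`, `z`, `hyper`), acceptance rates, and the run protocol.
#' @export
fit_mcmc <- function(data, model = c("1PL", "2PL"), prior,
                     chains = 1, burnin = 5000, keep = 1000, seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(prior, "irt_prior"))
  if (prior$regime == "none") stop("MCMC requires a proper prior regime")
  if (keep <= 0) stop("keep must be positive")
  if (chains < 1) stop("chains must be >= 1")
  Y <- as_response_matrix(data)
  check_binary_matrix(Y)

  regime <- if (prior$regime == "hierarchical") 1L else 0L
  thm <- 0; thv <- 1; bm <- 0; bv <- 1; zm <- 0; zv <- 0.0625
  hv <- 1e6; gs <- 1; gr <- 1
  if (regime == 0L) {
    thm <- prior$theta["mean"]; thv <- prior$theta["var"]
    bm <- prior$b["mean"]; bv <- prior$b["var"]
    if (model == "2PL") {
      zm <- prior$loga["mean"]; zv <- prior$loga["var"]
    }
  } else {
    hv <- prior$hyper_mean["var"]
    gs <- prior$hyper_prec["shape"]; gr <- prior$hyper_prec["rate"]
  }
  b_prop_init <- if (prior$regime == "stdvague") 2.5 else 1.0

  runs <- vector("list", chains)
  chain_seeds <- integer(chains)
  for (ch in seq_len(chains)) {
    chain_seeds[ch] <- mix_seed(seed, 104729, ch)
    set.seed(chain_seeds[ch])
    runs[[ch]] <- .gibbs_irt_cpp(Y, model_code(model), regime,
                                 thm, thv, bm, bv, zm, zv, hv, gs, gr,
                                 as.integer(burnin), as.integer(keep),
                                 b_prop_init)
  }

  structure(list(
    theta = lapply(runs, `[[`, "theta"),
    b = lapply(runs, `[[`, "b"),
    z = if (model == "2PL") lapply(runs, `[[`, "z") else NULL,
    hyper = if (regime == 1L) lapply(runs, `[[`, "hyper") else NULL,
    acceptance = data.frame(
      chain = seq_len(chains),
      theta = vapply(runs, `[[`, numeric(1), "acc_theta"),
      b = vapply(runs, `[[`, numeric(1), "acc_b"),
      z = vapply(runs, `[[`, numeric(1), "acc_z")),
    model = model, prior = prior$regime, burnin = burnin, keep = keep,
    chains = chains, seeds = chain_seeds), class = "irt_chains")
}

#' @export
print.irt_chains <- function(x, ...) {
  cat(sprintf("irt_chains: %s, %s prior, %d chain(s), burn-in %d, kept %d\n",
              x$model, x$prior, x$chains, x$burnin, x$keep))
  cat(sprintf("  acceptance (theta/b): %.2f / %.2f\n",
              mean(x$acceptance$theta), mean(x$acceptance$b)))
  invisible(x)
}

# stack retained draws of one parameter family across chains
pool_draws <- function(draws_list) do.call(rbind, draws_list)

#' Posterior summaries of retained draws
#'
#' Point estimate = pooled posterior mean across chains; SE = pooled
#' posterior standard deviation (n-1 divisor). Discriminations are
#' summarized on the natural scale, `a = exp(z)` applied draw by draw.
#'
#' @param draws an `irt_chains` object with at least 2 retained draws.
#' @return An [irt_estimates] object (method `"MCMC"`).
#' @export
summarize_chains <- function(draws) {
  stopifnot(inherits(draws, "irt_chains"))
  if (draws$keep < 2) stop("need at least 2 retained draws")
  th <- pool_draws(draws$theta)
  b <- pool_draws(draws$b)
  est <- list(theta = colMeans(th), b = colMeans(b),
              se_theta = apply(th, 2, sd), se_b = apply(b, 2, sd))
  if (draws$model == "2PL") {
    adr <- exp(pool_draws(draws$z))
    a <- colMeans(adr)
    se_a <- apply(adr, 2, sd)
  } else {
    a <- rep(1, ncol(b))
    se_a <- rep(0, ncol(b))
  }
  irt_estimates(theta = est$theta, b = est$b, a = a,
                se_theta = est$se_theta, se_b = est$se_b, se_a = se_a,
                method = "MCMC", prior = draws$prior, model = draws$model,
                details = list(burnin = draws$burnin, keep = draws$keep,
                               chains = draws$chains,
                               acceptance = draws$acceptance))
}

get_param_draws <- function(draws, family, index) {
  fam <- draws[[family]]
  if (is.null(fam)) stop(sprintf("no '%s' draws in this object", family))
  lapply(fam, function(m) m[, index])
}

#' Potential scale reduction factor (PSRF) of one parameter
#'
#' Between/within-chain variance ratio with the Brooks-Gelman correction,
#' as used to declare convergence when its 0.975 quantile falls below 1.2.
#' Requires at least two chains of equal length.
#'
#' @param draws an `irt_chains` object.
#' @param family one of `"theta"`, `"b"`, `"z"`, `"hyper"`.
#' @param index column index of the parameter within the family.
#' @return A list with `point` and `upper` (0.975 quantile) PSRF values.
#' @export
psrf <- function(draws, family = c("theta", "b", "z", "hyper"), index = 1) {
  family <- match.arg(family)
  stopifnot(inherits(draws, "irt_chains"))
  if (draws$chains < 2) {
    stop("PSRF requires at least two chains")
  }
  ch <- get_param_draws(draws, family, index)
  m <- length(ch)
  n <- length(ch[[1]])
  W <- mean(vapply(ch, var, numeric(1)))
  B <- n * var(vapply(ch, mean, numeric(1)))
  if (W == 0) {
    return(list(point = 1, upper = 1))
  }
  # Brooks-Gelman corrected estimator; equals sqrt((n-1)/n) when B = 0
  point <- sqrt((m + 1) / m * ((n - 1) / n + B / (n * W)) -
                  (n - 1) / (m * n))
  upper <- tryCatch({
    ml <- coda::mcmc.list(lapply(ch, coda::mcmc))
    gd <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)
    unname(gd$psrf[1, 2])
  }, error = function(e) NA_real_)
  if (!is.finite(upper)) upper <- point
  list(point = point, upper = upper)
}

#' Multivariate PSRF over item parameters and hyperparameters
#'
#' @param draws an `irt_chains` object with >= 2 chains.
#' @return The multivariate potential scale reduction factor.
#' @export
mpsrf <- function(draws) {
  stopifnot(inherits(draws, "irt_chains"))
  if (draws$chains < 2) stop("MPSRF requires at least two chains")
  block <- function(ch) {
    m <- draws$b[[ch]]
    if (!is.null(draws$z)) m <- cbind(m, draws$z[[ch]])
    if (!is.null(draws$hyper)) m <- cbind(m, draws$hyper[[ch]])
    m
  }
  mats <- lapply(seq_len(draws$chains), block)
  keepcol <- apply(mats[[1]], 2, function(col) sd(col) > 0)
  ml <- coda::mcmc.list(lapply(mats, function(m) {
    coda::mcmc(m[, keepcol, drop = FALSE])
  }))
  coda::gelman.diag(ml, autoburnin = FALSE, multivariate = TRUE)$mpsrf
}

#' Heidelberger-Welch half-width test for a single chain
#'
#' Stationarity is assessed by the Cramer-von Mises statistic on increasing
#' discard fractions; if the retained portion passes, the half-width of the
#' spectral-density CI of the mean is compared to `eps` times the mean.
#' A constant chain passes trivially.
#'
#' @param chain numeric vector of draws (length >= 100).
#' @param alpha significance level of the stationarity test.
#' @param eps target relative half-width.
#' @return A list with logical `pass`, `stationarity`, `halfwidth`.
#' @export
halfwidth_test <- function(chain, alpha = 0.05, eps = 0.1) {
  if (length(chain) < 100) stop("chain too short for the half-width test")
  if (sd(chain) == 0) {
    return(list(pass = TRUE, stationarity = TRUE, halfwidth = TRUE))
  }
  hd <- coda::heidel.diag(coda::mcmc(chain), eps = eps, pvalue = alpha)
  st <- isTRUE(hd[1, "stest"] == 1)
  hw <- isTRUE(hd[1, "htest"] == 1)
  list(pass = st && hw, stationarity = st, halfwidth = hw)
}

#' Persist retained draws as long-format CSV
#'
#' Audit companion to [fit_mcmc]: every retained draw of every parameter is
#' written as one row with columns `iteration`, `chain`, `parameter`,
#' `value` (parameters named `theta[i]`, `b[k]`, `z[k]`, and the
#' hierarchical `m_theta`, `u_theta`, `m_b`, `u_b`, `m_a`, `u_a`).
#'
#' @param draws an `irt_chains` object.
#' @param path file path; a `.gz` suffix writes through a gzip connection.
#' @return The path, invisibly.
#' @export
write_chains <- function(draws, path) {
  stopifnot(inherits(draws, "irt_chains"))
  hyper_names <- c("m_theta", "u_theta", "m_b", "u_b", "m_a", "u_a")
  one_family <- function(mat, labels, chain) {
    data.frame(iteration = rep(seq_len(nrow(mat)), ncol(mat)),
               chain = chain,
               parameter = rep(labels, each = nrow(mat)),
               value = as.vector(mat))
  }
  out <- list()
  for (ch in seq_len(draws$chains)) {
    out[[length(out) + 1]] <- one_family(
      draws$theta[[ch]], sprintf("theta[%d]", seq_len(ncol(draws$theta[[ch]]))), ch)
    out[[length(out) + 1]] <- one_family(
      draws$b[[ch]], sprintf("b[%d]", seq_len(ncol(draws$b[[ch]]))), ch)
    if (!is.null(draws$z)) {
      out[[length(out) + 1]] <- one_family(
        draws$z[[ch]], sprintf("z[%d]", seq_len(ncol(draws$z[[ch]]))), ch)
    }
    if (!is.null(draws$hyper)) {
      keep <- if (draws$model == "2PL") 1:6 else 1:4
      out[[length(out) + 1]] <- one_family(
        draws$hyper[[ch]][, keep, drop = FALSE], hyper_names[keep], ch)
    }
  }
  df <- do.call(rbind, out)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
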