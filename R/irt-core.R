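#' Item response function of the 2PL (and 1PL) logistic model
#'
#' Probability of a correct response for ability `theta` on an item with
#' difficulty `b` and discrimination `a`:
#' `P = exp(a(theta - b)) / (1 + exp(a(theta - b)))`. Computed through the
#' numerically stable logistic so logits up to +/-700 are safe. Arguments
#' recycle as usual.
#'
#' @param theta ability (logit scale).
#' @param b item difficulty.
#' @param a item discrimination, strictly positive.
#' @return Probability in (0, 1).
#' @examples
#' irf(0, 0, 1) # 0.5
#' irf(1, 0, 1) # plogis(1)
#' @export
irf <- function(theta, b, a = 1) {
  if (any(a <= 0)) stop("discrimination must be strictly positive")
  plogis(a * (theta - b))
}

# S x L matrix of response probabilities
irf_matrix <- function(theta, b, a = rep(1, length(b))) {
  plogis(outer(theta, b, "-") * rep(a, each = length(theta)))
}

#' Bernoulli log-likelihood of a response matrix
#'
#' Sum over persons and items of `y log p + (1 - y) log(1 - p)` with `p`
#' from [irf], assuming local independence.
#'
#' @param data S x L binary response matrix.
#' @param params an [irt_parameters] or [irt_estimates] object (fields
#'   `theta`, `b`, `a`) with dimensions matching `data`.
#' @return The log-likelihood (scalar).
#' @export
response_loglik <- function(data, params) {
  Y <- as_response_matrix(data)
  if (nrow(Y) != length(params$theta) || ncol(Y) != length(params$b)) {
    stop("dimension mismatch between responses and parameters")
  }
  eta <- outer(params$theta, params$b, "-") *
    rep(params$a, each = nrow(Y))
  # log p = log sigmoid(eta), log(1-p) = log sigmoid(-eta), both stable
  sum(Y * plogis(eta, log.p = TRUE) + (1 - Y) * plogis(-eta, log.p = TRUE))
}

#' Prior configurations for Bayesian 1PL/2PL estimation
#'
#' Returns the prior regime used by the MCMC and VB fitters. All normal and
#' lognormal priors are parameterized as (mean, variance); hierarchical
#' regimes place normal(0, 1e6) hyperpriors on the population means and
#' Gamma(shape 1, rate 1) hyperpriors on the population precisions.
#'
#' The regimes are:
#' \describe{
#'   \item{matched}{theta, b ~ N(0, 1); a ~ lognormal(0, sd 0.25), i.e.
#'     log a ~ N(0, 0.0625) — identical to the generating distributions.}
#'   \item{stdvague}{theta ~ N(0, 1); b ~ N(0, 1e3); log a ~ N(0, 8).}
#'   \item{hierarchical}{theta ~ N(m_theta, 1/u_theta), b ~ N(m_b, 1/u_b),
#'     log a ~ N(m_a, 1/u_a), with m ~ N(0, 1e6) and u ~ Gamma(1, 1).}
#'   \item{none}{no prior; only valid for CML/MML.}
#' }
#'
#' @param regime one of `"matched"`, `"stdvague"`, `"hierarchical"`, `"none"`.
#' @param model `"1PL"` or `"2PL"`; the 1PL carries no discrimination prior.
#' @return An object of class `irt_prior`.
#' @export
make_prior <- function(regime = c("matched", "stdvague", "hierarchical",
                                  "none"),
                       model = c("1PL", "2PL")) {
  regime <- match.arg(regime)
  model <- match.arg(model)
  pr <- list(regime = regime, model = model)
  if (regime == "matched") {
    pr$theta <- c(mean = 0, var = 1)
    pr$b <- c(mean = 0, var = 1)
    if (model == "2PL") pr$loga <- c(mean = 0, var = 0.25^2)
  } else if (regime == "stdvague") {
    pr$theta <- c(mean = 0, var = 1)
    pr$b <- c(mean = 0, var = 1e3)
    if (model == "2PL") pr$loga <- c(mean = 0, var = 8)
  } else if (regime == "hierarchical") {
    pr$hyper_mean <- c(mean = 0, var = 1e6)
    pr$hyper_prec <- c(shape = 1, rate = 1)
  }
  structure(pr, class = "irt_prior")
}

#' @export
print.irt_prior <- function(x, ...) {
  cat(sprintf("irt_prior: %s (%s)\n", x$regime, x$model))
  invisible(x)
}

#' Parameter estimates with standard errors
#'
#' Container shared by every fitter: point estimates and SEs for abilities,
#' difficulties, and discriminations, plus a method/prior tag. For 1PL fits
#' the discriminations are fixed at 1 with SE 0.
#'
#' @param theta,b,a point estimates.
#' @param se_theta,se_b,se_a nonnegative standard errors.
#' @param method estimation method tag, e.g. `"CML"`, `"VB"`.
#' @param prior prior regime tag, e.g. `"matched"`, `"none"`.
#' @param model `"1PL"` or `"2PL"`.
#' @param details optional list of fitter diagnostics.
#' @return An object of class `irt_estimates`.
#' @export
irt_estimates <- function(theta, b, a, se_theta, se_b, se_a,
                          method, prior, model, details = list()) {
  stopifnot(length(theta) == length(se_theta),
            length(b) == length(se_b), length(a) == length(se_a),
            length(a) == length(b))
  if (any(c(se_theta, se_b, se_a) < 0)) stop("SEs must be nonnegative")
  structure(list(theta = as.numeric(theta), b = as.numeric(b),
                 a = as.numeric(a), se_theta = as.numeric(se_theta),
                 se_b = as.numeric(se_b), se_a = as.numeric(se_a),
                 method = method, prior = prior, model = model,
                 details = details),
            class = "irt_estimates")
}

#' @export
print.irt_estimates <- function(x, ...) {
  cat(sprintf("irt_estimates: %s (%s prior), %s, %d persons x %d items\n",
              x$method, x$prior, x$model, length(x$theta), length(x$b)))
  cat(sprintf("  difficulty range [%.2f, %.2f], mean ability %.3f\n",
              min(x$b), max(x$b), mean(x$theta)))
  invisible(x)
}

#' Write / read estimates as long CSV
#'
#' Columns: `kind`, `index`, `estimate`, `se`, `method`, `prior`.
#'
#' @param est an [irt_estimates] object.
#' @param path file path.
#' @export
write_estimates <- function(est, path) {
  stopifnot(inherits(est, "irt_estimates"))
  df <- rbind(
    data.frame(kind = "ability", index = seq_along(est$theta),
               estimate = est$theta, se = est$se_theta),
    data.frame(kind = "difficulty", index = seq_along(est$b),
               estimate = est$b, se = est$se_b),
    data.frame(kind = "discrimination", index = seq_along(est$a),
               estimate = est$a, se = est$se_a))
  df$method <- est$method
  df$prior <- est$prior
  df$model <- est$model
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- read.csv(path)
  pick <- function(kind, col) df[[col]][df$kind == kind]
  irt_estimates(theta = pick("ability", "estimate"),
                b = pick("difficulty", "estimate"),
                a = pick("discrimination", "estimate"),
                se_theta = pick("ability", "se"),
                se_b = pick("difficulty", "se"),
                se_a = pick("discrimination", "se"),
                method = df$method[1], prior = df$prior[1],
                model = df$model[1])
}

# clamp applied to persons with raw score 0 (lower) or L (upper): the ML
# ability estimate diverges there, so the estimate is pinned at -/+4 logits
# and the SE evaluated at the clamp. All persons are retained downstream.
ML_ABILITY_CLAMP <- 4.0

#' Maximum-likelihood ability scoring with fixed item parameters
#'
#' Per-person Newton maximization of the Bernoulli likelihood in theta given
#' item difficulties and discriminations. Standard errors come from the test
#' information at the estimate, `SE = 1/sqrt(I(theta))`. Persons with an
#' extreme raw score (0 or perfect) have no finite maximizer; their estimate
#' is clamped to -4/+4 logits and the SE is evaluated at the clamp.
#'
#' @param data S x L binary response matrix.
#' @param b item difficulties.
#' @param a item discriminations (default all 1).
#' @return A list with `theta`, `se`, and logical `extreme` flags.
#' @export
ml_abilities <- function(data, b, a = rep(1, length(b))) {
  Y <- as_response_matrix(data)
  if (ncol(Y) != length(b) || length(a) != length(b)) {
    stop("item parameter lengths must match the response matrix")
  }
  S <- nrow(Y)
  L <- ncol(Y)
  raw <- as.integer(rowSums(Y))
  extreme <- raw == 0L | raw == L

  theta <- numeric(S)
  onepl <- all(a == a[1])
  if (onepl) {
    # under equal slopes the ML score depends on the raw score only
    scores <- sort(unique(raw[!extreme]))
    th_by_score <- vapply(scores, function(r) {
      ml_theta_newton(r, b, a)
    }, numeric(1))
    theta[!extreme] <- th_by_score[match(raw[!extreme], scores)]
  } else {
    idx <- which(!extreme)
    if (length(idx)) {
      theta[idx] <- ml_theta_newton_rows(Y[idx, , drop = FALSE], b, a)
    }
  }
  theta[raw == 0L] <- -ML_ABILITY_CLAMP
  theta[raw == L] <- ML_ABILITY_CLAMP

  P <- irf_matrix(theta, b, a)
  info <- drop((P * (1 - P)) %*% (a^2))
  list(theta = theta, se = 1 / sqrt(info), extreme = extreme)
}

# Newton solve of sum_k a_k p_k(theta) = r (1-D concave log-likelihood)
ml_theta_newton <- function(r, b, a, tol = 1e-10, maxit = 100) {
  th <- 0
  for (it in seq_len(maxit)) {
    p <- irf(th, b, a)
    g <- r - sum(a * p)
    if (abs(g) < tol) break
    info <- sum(a^2 * p * (1 - p))
    step <- g / info
    step <- max(min(step, 2), -2) # cap huge early steps
    th <- th + step
  }
  th
}

# vectorized Newton across persons for unequal slopes
ml_theta_newton_rows <- function(Y, b, a, tol = 1e-10, maxit = 100) {
  th <- numeric(nrow(Y))
  wa <- drop(Y %*% a) # sum_k a_k y_ik, fixed
  for (it in seq_len(maxit)) {
    P <- irf_matrix(th, b, a)
    g <- wa - drop(P %*% a)
    if (max(abs(g)) < tol) break
    info <- drop((P * (1 - P)) %*% (a^2))
    step <- pmax(pmin(g / info, 2), -2)
    th <- th + step
  }
  th
}
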