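#' Elementary symmetric functions of item easiness parameters
#'
#' Computes `gamma[r]`, the sum over all r-subsets of items of the product of
#' easiness values `eps = exp(-b)`, for r = 0..L, together with the
#' first-order partials `gamma_partial[k, r+1] = gamma_r` of the item set
#' with item k removed. The summation recursion is used; internally the
#' easiness vector is scaled by its geometric mean (gamma_r(c eps) = c^r
#' gamma_r(eps)) so the table stays balanced, and the returned values are
#' rescaled back.
#'
#' @param easiness strictly positive vector of length L.
#' @return A list of class `esf_table` with `gamma` (length L+1) and
#'   `gamma_partial` (L x L; row k holds orders 0..L-1 of the reduced set).
#' @examples
#' elementary_symmetric(c(1, 1, 1))$gamma # binomial coefficients 1 3 3 1
#' @export
elementary_symmetric <- function(easiness) {
  if (length(easiness) < 1 || any(easiness <= 0) || any(!is.finite(easiness))) {
    stop("easiness values must be strictly positive and finite")
  }
  L <- length(easiness)
  c0 <- exp(mean(log(easiness)))
  tab <- .esf_table_cpp(easiness / c0)
  gamma <- tab$gamma * c0^(0:L)
  gp <- tab$gamma_partial * rep(c0^(0:(L - 1)), each = L)
  structure(list(gamma = gamma, gamma_partial = gp, easiness = easiness),
            class = "esf_table")
}

#' Conditional maximum likelihood estimation of the Rasch (1PL) model
#'
#' Item difficulties are estimated by maximizing the likelihood of the
#' responses conditional on the raw scores (which are sufficient for ability
#' under the 1PL), eliminating the person parameters. Persons with extreme
#' raw scores (0 or perfect) carry no conditional information and are
#' excluded from item estimation. The difficulties are normalized to sum to
#' zero; their SEs come from the inverse observed information of the
#' conditional log-likelihood mapped through the sum-to-zero constraint.
#' Abilities for all persons (extreme scores included, clamped at +/-4) are
#' then scored by [ml_abilities] using the CML difficulties.
#'
#' Newton-Raphson with analytic gradient and Hessian built from the
#' elementary symmetric functions; convergence when the largest absolute
#' gradient element falls below 1e-8, with step-halving on non-increase.
#'
#' @param data S x L binary response matrix.
#' @return An [irt_estimates] object (method `"CML"`).
#' @export
fit_cml <- function(data) {
  Y <- as_response_matrix(data)
  S <- nrow(Y)
  L <- ncol(Y)
  raw <- rowSums(Y)
  keep <- raw > 0 & raw < L
  Yk <- Y[keep, , drop = FALSE]
  if (nrow(Yk) == 0) stop("no non-extreme response patterns; cannot fit CML")

  item_tot <- colSums(Yk)
  bad <- item_tot == 0 | item_tot == nrow(Yk)
  if (any(bad)) {
    stop(sprintf("degenerate item(s) %s: all responses identical among %s",
                 paste(which(bad), collapse = ", "),
                 "non-extreme persons"))
  }
  score_counts <- tabulate(rowSums(Yk) + 1L, nbins = L + 1L)

  # beta = log easiness = -difficulty; beta[1] fixed at 0 for identification
  beta <- rep(0, L)
  free <- 2:L
  d <- .cml_derivs_cpp(beta, score_counts, item_tot, TRUE)
  for (it in seq_len(100)) {
    g <- d$gradient[free]
    if (max(abs(g)) < 1e-8) break
    H <- d$hessian[free, free, drop = FALSE]
    step <- tryCatch(solve(H, -g), error = function(e) -g / diag(H))
    lambda <- 1
    repeat {
      cand <- beta
      cand[free] <- beta[free] + lambda * step
      dn <- .cml_derivs_cpp(cand, score_counts, item_tot, TRUE)
      if (dn$loglik >= d$loglik - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    beta <- cand
    d <- dn
  }
  if (max(abs(d$gradient[free])) > 1e-6) {
    warning("CML Newton did not reach gradient tolerance")
  }

  # sum-to-zero difficulties and their covariance
  b_raw <- -beta
  b_hat <- b_raw - mean(b_raw)
  V_free <- solve(-d$hessian[free, free, drop = FALSE])
  # b_centered = M %*% beta_free with beta_full = (0, beta_free)
  M <- matrix(1 / L, L, L - 1)
  M[cbind(free, seq_len(L - 1))] <- M[cbind(free, seq_len(L - 1))] - 1
  V_b <- M %*% V_free %*% t(M)
  se_b <- sqrt(pmax(diag(V_b), 0))

  ab <- ml_abilities(Y, b_hat, rep(1, L))
  irt_estimates(theta = ab$theta, b = b_hat, a = rep(1, L),
                se_theta = ab$se, se_b = se_b, se_a = rep(0, L),
                method = "CML", prior = "none", model = "1PL",
                details = list(conditional_loglik = d$loglik,
                               iterations = it,
                               extreme_persons = sum(!keep)))
}
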