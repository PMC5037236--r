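#' Quadrature grid over the ability distribution
#'
#' Equally spaced nodes with standard-normal density weights renormalized to
#' sum to one — the conventional fixed-grid approximation to the N(0, 1)
#' ability distribution in marginal maximum likelihood.
#'
#' @param n number of nodes (default 41).
#' @param bounds symmetric interval for the nodes.
#' @return A list of class `quadrature_grid` with `nodes` and `weights`.
#' @export
quadrature_grid <- function(n = 41, bounds = c(-5, 5)) {
  stopifnot(n >= 3, bounds[1] < 0, bounds[2] == -bounds[1])
  nodes <- seq(bounds[1], bounds[2], length.out = n)
  w <- dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)),
            class = "quadrature_grid")
}

#' Marginal maximum likelihood estimation (Bock-Aitkin EM)
#'
#' Item parameters are estimated by integrating the response likelihood over
#' a fixed N(0, 1) ability distribution (approximated on `grid`) and
#' maximizing with respect to the item parameters via EM: the E-step forms
#' posterior node weights per person, the M-step runs per-item weighted
#' logistic Newton updates (slope fixed at 1 for the 1PL). The marginal
#' log-likelihood is non-decreasing across cycles and is returned as a
#' trace. Item SEs use the per-person score outer products of the marginal
#' likelihood (cross-item blocks ignored); abilities are then scored by
#' [ml_abilities].
#'
#' @param data S x L binary response matrix.
#' @param model `"1PL"` or `"2PL"`.
#' @param grid a [quadrature_grid].
#' @param tol stop when the largest absolute item-parameter change in one
#'   cycle falls below this value.
#' @param max_cycles cycle cap.
#' @return An [irt_estimates] object (method `"MML"`).
#' @export
fit_mml <- function(data, model = c("1PL", "2PL"), grid = quadrature_grid(),
                    tol = 1e-5, max_cycles = 500) {
  model <- match.arg(model)
  Y <- as_response_matrix(data)
  S <- nrow(Y)
  L <- ncol(Y)
  ct <- colSums(Y)
  if (any(ct == 0 | ct == S)) {
    stop(sprintf("degenerate item(s) %s: all responses identical",
                 paste(which(ct == 0 | ct == S), collapse = ", ")))
  }
  x <- grid$nodes
  w <- grid$weights
  Q <- length(x)

  b <- qlogis(pmin(pmax(1 - ct / S, 0.01), 0.99)) # classical starting values
  a <- rep(1, L)
  trace <- numeric(0)
  flagged <- FALSE

  estep <- function(b, a) {
    eta <- outer(-b, x, "+") * a          # L x Q logits a_k (x_q - b_k)
    logP <- plogis(eta, log.p = TRUE)
    logQm <- plogis(-eta, log.p = TRUE)
    lf <- Y %*% logP + (1 - Y) %*% logQm  # S x Q
    lf <- sweep(lf, 2, log(w), "+")
    mx <- apply(lf, 1, max)
    ef <- exp(lf - mx)
    denom <- rowSums(ef)
    list(post = ef / denom, loglik = sum(mx + log(denom)),
         P = plogis(eta))
  }

  for (cycle in seq_len(max_cycles)) {
    es <- estep(b, a)
    trace <- c(trace, es$loglik)
    nq <- colSums(es$post)            # expected persons per node
    R <- crossprod(Y, es$post)        # L x Q expected correct per item/node

    b_old <- b
    a_old <- a
    # expected complete-data objective, summed over items
    mobj <- function(eta) {
      sum(R * plogis(eta, log.p = TRUE)) +
        sum((rep(nq, each = L) - R) * plogis(-eta, log.p = TRUE))
    }
    if (model == "1PL") {
      f0 <- mobj(outer(-b, x, "+"))
      for (nt in seq_len(50)) {
        P <- plogis(outer(-b, x, "+"))
        g <- rowSums(R) - drop(P %*% nq)      # d obj / d(-b) sign folded below
        h <- drop((P * (1 - P)) %*% nq)
        if (max(abs(g)) < 1e-10) break
        step <- pmax(pmin(-g / h, 1), -1)     # Newton step in b
        lambda <- 1
        repeat {
          cand <- b + lambda * step
          f1 <- mobj(outer(-cand, x, "+"))
          if (f1 >= f0 - 1e-12 || lambda < 1e-4) break
          lambda <- lambda / 2
        }
        b <- cand
        f0 <- f1
      }
    } else {
      # per-item Newton on (intercept c, slope a), logit = c + a x, b = -c/a
      cc <- -b * a
      f0 <- mobj(outer(cc, rep(1, Q)) + outer(a, x))
      for (nt in seq_len(50)) {
        eta <- outer(cc, rep(1, Q)) + outer(a, x)
        P <- plogis(eta)
        Dev <- R - P * rep(nq, each = L)      # L x Q residual counts
        g1 <- rowSums(Dev)
        g2 <- drop(Dev %*% x)
        if (max(abs(c(g1, g2))) < 1e-10) break
        Wq <- P * (1 - P) * rep(nq, each = L)
        h11 <- rowSums(Wq)
        h12 <- drop(Wq %*% x)
        h22 <- drop(Wq %*% x^2)
        det <- pmax(h11 * h22 - h12^2, 1e-12)
        s1 <- pmax(pmin((h22 * g1 - h12 * g2) / det, 1), -1)
        s2 <- pmax(pmin((h11 * g2 - h12 * g1) / det, 0.5), -0.5)
        lambda <- 1
        repeat {
          cand_c <- cc + lambda * s1
          cand_a <- pmax(a + lambda * s2, 1e-3)
          f1 <- mobj(outer(cand_c, rep(1, Q)) + outer(cand_a, x))
          if (f1 >= f0 - 1e-12 || lambda < 1e-4) break
          lambda <- lambda / 2
        }
        cc <- cand_c
        a <- cand_a
        f0 <- f1
      }
      b <- -cc / a
    }

    # Heywood-type guard
    if (any(abs(b) > 10) || any(a > 20)) {
      flagged <- TRUE
      b <- pmax(pmin(b, 10), -10)
      a <- pmin(a, 20)
    }
    if (max(abs(c(b - b_old, a - a_old))) < tol) break
  }

  es <- estep(b, a)
  trace <- c(trace, es$loglik)

  # empirical information from per-person marginal score contributions
  T1 <- Y - es$post %*% t(es$P)                       # S x L
  px <- es$post %*% t(es$P * rep(x, each = L))        # S x L of E[p x]
  T2 <- Y * drop(es$post %*% x) - px
  if (model == "1PL") {
    se_b <- 1 / sqrt(colSums(T1^2))
    se_a <- rep(0, L)
  } else {
    sb <- -T1 * rep(a, each = S)
    sa <- T2 - T1 * rep(b, each = S)
    i11 <- colSums(sb^2)
    i12 <- colSums(sb * sa)
    i22 <- colSums(sa^2)
    det <- i11 * i22 - i12^2
    se_b <- sqrt(pmax(i22 / det, 0))
    se_a <- sqrt(pmax(i11 / det, 0))
  }

  ab <- ml_abilities(Y, b, a)
  irt_estimates(theta = ab$theta, b = b, a = a,
                se_theta = ab$se, se_b = se_b, se_a = se_a,
                method = "MML", prior = "none", model = model,
                details = list(loglik_trace = trace, cycles = cycle,
                               flagged = flagged))
}
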